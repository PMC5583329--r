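# shared fixtures and independent oracles

# a gene model collinear with the reference: identity alignment, coding
# offsets chosen directly
make_collinear_gene <- function(offsets = c(574, 673, 900),
                                intron_lengths = rep(100, length(offsets)),
                                n_codons = 403, gene_id = "G1") {
  cds_len <- 3 * n_codons
  stopifnot(all(offsets > 0), all(offsets < cds_len))
  exon_lens <- diff(c(0, sort(offsets), cds_len))
  starts <- integer(length(exon_lens)); ends <- integer(length(exon_lens))
  pos <- 0L
  for (i in seq_along(exon_lens)) {
    starts[i] <- pos; ends[i] <- pos + exon_lens[i]
    pos <- ends[i] + if (i <= length(intron_lengths)) intron_lengths[i] else 0L
  }
  gene_model(gene_id = gene_id, seq_id = "chr1", strand = "+",
             cds_exons = cbind(starts, ends))
}

# identity alignment: gene row == reference row (protein of n_codons - 1
# residues; the stop codon has no residue)
make_identity_alignment <- function(n_codons = 403, gene_id = "G1",
                                    seed = 11) {
  set.seed(seed)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  prot <- paste(sample(aa, n_codons - 1, replace = TRUE), collapse = "")
  rows <- stats::setNames(c(prot, prot), c(gene_id, "REF"))
  multiple_alignment(rows, reference_name = "REF")
}

# gene model with explicitly chosen exon sizes (for size-edit tests where the
# printed serpin exon sizes, not reference collinearity, are the point)
make_sized_gene <- function(exon_sizes = c(574, 99, 233, 303),
                            intron_lengths = rep(100, length(exon_sizes) - 1),
                            gene_id = "G1") {
  starts <- integer(length(exon_sizes)); ends <- integer(length(exon_sizes))
  pos <- 0L
  for (i in seq_along(exon_sizes)) {
    starts[i] <- pos; ends[i] <- pos + exon_sizes[i]
    pos <- ends[i] + if (i < length(exon_sizes)) intron_lengths[i] else 0L
  }
  gene_model(gene_id = gene_id, seq_id = "chr1", strand = "+",
             cds_exons = cbind(starts, ends))
}

# independent oracle: find codon number and remainder by walking the CDS
# nucleotide by nucleotide
codon_walk <- function(offset) {
  codon <- 1L; in_codon <- 0L
  for (i in seq_len(offset)) {
    in_codon <- in_codon + 1L
    if (in_codon == 4L) { codon <- codon + 1L; in_codon <- 1L }
  }
  c(codon = codon, remainder = in_codon)
}

# independent Dollo oracle: exhaustive enumeration of gain placements; for
# each, losses are the maximal all-absent subtrees, computed from leaf
# descendant sets (a different route than the package's postorder counts)
dollo_oracle <- function(tree, presence) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  p <- presence[tree$tip.label]
  desc <- vector("list", nn)
  fill <- function(v) {
    if (v <= ntip) { desc[[v]] <<- v; return(v) }
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    desc[[v]] <<- unlist(lapply(kids, fill))
    desc[[v]]
  }
  fill(ntip + 1L)

  present_tips <- which(!is.na(p) & p == 1)
  if (length(present_tips) == 0) return(list(gain = NA, losses = NA, min_losses = 0))
  best <- NULL
  for (g in seq_len(nn)) {
    leaves <- desc[[g]]
    if (!all(present_tips %in% leaves)) next  # gain must cover all present
    # losses: maximal subtrees below g with no present and >=1 absent leaf
    losses <- integer(0)
    walk <- function(v) {
      kids <- tree$edge[tree$edge[, 1] == v, 2]
      for (ch in kids) {
        lv <- desc[[ch]]
        pres <- sum(!is.na(p[lv]) & p[lv] == 1)
        abs_ <- sum(!is.na(p[lv]) & p[lv] == 0)
        if (pres == 0) {
          if (abs_ > 0) losses <<- c(losses, ch)
        } else if (ch > ntip) walk(ch)
      }
    }
    if (g > ntip) walk(g)
    if (is.null(best) || length(losses) < length(best$losses))
      best <- list(gain = g, losses = losses)
  }
  list(gain = best$gain, losses = best$losses,
       min_losses = length(best$losses))
}

# random labelled species tree with integer-ish MY branch lengths
random_species_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n, tip.label = paste0("sp", seq_len(n)))
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) * 300
  tr$node.label <- paste0("N", seq_len(tr$Nnode))
  tr
}
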