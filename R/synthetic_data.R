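#' Bundled vertebrate-like species tree fixture
#'
#' An 11-taxon time-calibrated (ultrametric, MY) species tree of one tetrapod
#' lineage plus ten ray-finned fishes, with labelled internal nodes
#' (Actinopterygii, Teleostei, Otophysa, Euteleostei, ...). Node ages place
#' the actinopterygian stem at 416-360 MY and the euteleost stem at
#' 231-190 MY, the windows in which gene-family duplications and the
#' lineage-restricted intron gains of the serpin study are dated.
#'
#' @return A rooted ultrametric `phylo` tree.
#' @export
fish_species_tree <- function() {
  path <- system.file("extdata", "fish_species_tree.nwk",
                      package = "introscape")
  if (path == "") stop("fixture tree not found; is the package installed?")
  ape::read.tree(path)
}

#' Default simulation configuration
#'
#' The defaults reproduce the study conditions the pipeline targets: a
#' single-copy focal gene with the conserved 4-exon/3-intron architecture
#' (introns at coding offsets 574/673/900, i.e. reference positions
#' 192a/225a/300c for a gene collinear with the reference), two duplications
#' on the actinopterygian stem yielding three paralog sets, and two intron
#' gains (offsets 107 and 305 -> labels 36b and 102b) on the euteleost stem
#' of the first copy only. The default substitution rate (5.25e-4
#' substitutions/site/MY) puts leaf-to-leaf identity across the root depth
#' in the low-to-mid 60s percent, the conserved-ortholog range reported for
#' this family.
#'
#' @param species_tree Ultrametric `phylo` with branch lengths in MY and
#'   labelled internal nodes; defaults to [fish_species_tree()].
#' @param substitution_rate Substitutions/site/MY.
#' @param root_protein_length Residues of the root protein (stop codon
#'   excluded; the CDS is `3*(L+1)` nt).
#' @param root_introns Data.frame with `offset` (coding nt 5' of each
#'   intron) and `length` (nt; NA = draw log-uniformly from 78-2096 nt, the
#'   span of vertebrate serpin intron sizes).
#' @param root_gene_id Identifier of the root gene copy.
#' @param root_locus A [locus()] giving the root flanking neighborhood.
#' @param events List of scripted events; each a list with `branch` (tip or
#'   internal-node label of the branch's child end), `type` (one of
#'   `"intron_gain"`, `"duplication"`, `"locus_shuffle"`, `"locus_loss"`,
#'   `"codon_indel"`), `gene` (copy id), and type-specific fields:
#'   `offset`/`length` (intron_gain), `new_id` (duplication), `symbol`
#'   (locus events), `exon`/`codons` (codon_indel).
#' @param seed Integer seed; every random draw in the simulation flows from
#'   it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(species_tree = fish_species_tree(),
                              substitution_rate = 5.25e-4,
                              root_protein_length = 402L,
                              root_introns = data.frame(
                                offset = c(574L, 673L, 900L),
                                length = NA_integer_),
                              root_gene_id = "HSP47_1",
                              root_locus = locus(
                                "root", "HSP47",
                                upstream = c("GDPD5", "KLHL35", "RPS3"),
                                downstream = c("MAP6", "DGAT2", "TSKU",
                                               "ACER3", "MYO7A")),
                              events = list(
                                list(branch = "Actinopterygii",
                                     type = "duplication",
                                     gene = "HSP47_1", new_id = "HSP47_3"),
                                list(branch = "Actinopterygii",
                                     type = "duplication",
                                     gene = "HSP47_1", new_id = "HSP47_2"),
                                list(branch = "Euteleostei",
                                     type = "intron_gain",
                                     gene = "HSP47_1", offset = 107L,
                                     length = NA_integer_),
                                list(branch = "Euteleostei",
                                     type = "intron_gain",
                                     gene = "HSP47_1", offset = 305L,
                                     length = NA_integer_)),
                              seed = 1L) {
  cds_len <- 3L * (root_protein_length + 1L)
  if (nrow(root_introns) &&
      (any(root_introns$offset < 1) || any(root_introns$offset >= cds_len)))
    stop("root intron offsets must lie inside the CDS (1..", cds_len - 1, ")")
  known <- c(species_tree$tip.label, species_tree$node.label)
  for (ev in events) {
    if (!ev$branch %in% known)
      stop("scripted event on unknown branch '", ev$branch, "'")
  }
  structure(list(species_tree = species_tree,
                 substitution_rate = substitution_rate,
                 root_protein_length = as.integer(root_protein_length),
                 root_introns = root_introns,
                 root_gene_id = root_gene_id,
                 root_locus = root_locus,
                 events = events, seed = as.integer(seed)),
            class = "simulation_config")
}

#' Expected percent identity under the uniform-replacement model
#'
#' Sequences evolve by per-site Poisson substitution at `rate`
#' substitutions/site/MY, each event replacing the residue uniformly among
#' the 19 alternatives. Two sequences separated by a path of `2*depth` MY
#' then share a site with probability `1/20 + (19/20) exp(-(20/19) rate 2
#' depth)` — the 20-state Jukes-Cantor analogue — which this helper returns
#' as a percentage. Use it (or [rate_for_identity()]) to pick rates that hit
#' target identities.
#'
#' @param rate Substitutions/site/MY.
#' @param depth MY from the common ancestor to each leaf (half the path).
#' @return Expected identity in percent.
#' @export
calibrate_identity <- function(rate, depth) {
  100 * (1 / 20 + (19 / 20) * exp(-(20 / 19) * rate * 2 * depth))
}

#' @rdname calibrate_identity
#' @param identity Target identity in percent.
#' @return `rate_for_identity`: the substitution rate achieving the target.
#' @export
rate_for_identity <- function(identity, depth) {
  p <- identity / 100
  if (p <= 1 / 20) stop("target identity at or below the 5% saturation floor")
  -log((p - 1 / 20) / (19 / 20)) * (19 / 20) / (2 * depth)
}

# ---- internal simulation machinery ------------------------------------------

aa_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

synonymous_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
}

sample_codons <- function(aa, syn) {
  vapply(aa, function(a) {
    cs <- syn[[a]]
    cs[sample.int(length(cs), 1)]
  }, "")
}

random_intron_length <- function(n = 1) {
  as.integer(round(exp(stats::runif(n, log(78), log(2096)))))
}

random_intron_seq <- function(len) {
  stopifnot(len >= 4)
  mid <- paste(sample(c("A", "C", "G", "T"), len - 4, replace = TRUE),
               collapse = "")
  paste0("GT", mid, "AG")
}

# evolve one gene copy along a branch of t MY; the C-terminal tetrapeptide
# (the ER-retention signal) is held invariant, emulating the purifying
# selection that keeps [RKH]DEL intact across the family
evolve_gene <- function(gene, rate, t, syn) {
  L <- length(gene$aa)
  if (L == 0 || t <= 0 || rate <= 0) return(gene)
  nsub <- stats::rpois(L, rate * t)
  if (L > 4) nsub[(L - 3):L] <- 0L
  hit <- which(nsub > 0)
  alpha <- aa_alphabet()
  for (i in hit) {
    for (k in seq_len(nsub[i])) {
      gene$aa[i] <- sample(setdiff(alpha, gene$aa[i]), 1)
    }
    gene$codons[i] <- sample_codons(gene$aa[i], syn)
  }
  gene
}

apply_sim_event <- function(state, ev, syn, log_env) {
  genes <- state$genes
  note <- function(...) {
    log_env$events[[length(log_env$events) + 1L]] <-
      c(list(branch = ev$branch, type = ev$type), ev[setdiff(names(ev), c("branch", "type"))])
  }
  g <- ev$gene
  if (!ev$type %in% c("duplication") && !g %in% names(genes))
    stop("event targets unknown gene copy '", g, "'")
  if (ev$type == "intron_gain") {
    len <- if (is.null(ev$length) || is.na(ev$length)) random_intron_length() else ev$length
    gi <- genes[[g]]
    cds_len <- 3L * (length(gi$aa) + 1L)
    if (ev$offset < 1 || ev$offset >= cds_len)
      stop("intron gain offset ", ev$offset, " outside the CDS")
    gi$introns <- rbind(gi$introns,
                        data.frame(offset = as.integer(ev$offset),
                                   length = as.integer(len),
                                   seq = random_intron_seq(len)))
    gi$introns <- gi$introns[order(gi$introns$offset), ]
    if (anyDuplicated(gi$introns$offset))
      stop("intron gain at an already occupied offset ", ev$offset)
    genes[[g]] <- gi
    ev$length <- len
  } else if (ev$type == "duplication") {
    if (!g %in% names(genes))
      stop("event targets unknown gene copy '", g, "'")
    new_id <- if (!is.null(ev$new_id)) ev$new_id else
      paste0(g, "dup", length(genes) + 1L)
    if (new_id %in% names(genes)) stop("duplicate copy id '", new_id, "'")
    genes[[new_id]] <- genes[[g]]
  } else if (ev$type == "locus_shuffle") {
    gi <- genes[[g]]
    sym <- toupper(ev$symbol)
    if (sym %in% gi$locus_up) {
      gi$locus_up <- setdiff(gi$locus_up, sym)
      gi$locus_dn <- c(sym, gi$locus_dn)
    } else if (sym %in% gi$locus_dn) {
      gi$locus_dn <- setdiff(gi$locus_dn, sym)
      gi$locus_up <- c(sym, gi$locus_up)
    } else stop("locus_shuffle: symbol '", sym, "' not at locus of ", g)
    genes[[g]] <- gi
  } else if (ev$type == "locus_loss") {
    gi <- genes[[g]]
    sym <- toupper(ev$symbol)
    if (sym == gi$focal_symbol) {
      gi$focal_present <- FALSE
    } else if (sym %in% c(gi$locus_up, gi$locus_dn)) {
      gi$locus_up <- setdiff(gi$locus_up, sym)
      gi$locus_dn <- setdiff(gi$locus_dn, sym)
    } else stop("locus_loss: symbol '", sym, "' not at locus of ", g)
    genes[[g]] <- gi
  } else if (ev$type == "codon_indel") {
    gi <- genes[[g]]
    cds_len <- 3L * (length(gi$aa) + 1L)
    bounds <- c(0L, gi$introns$offset, cds_len)
    if (ev$exon < 1 || ev$exon > length(bounds) - 1) stop("codon_indel: no such exon")
    n <- as.integer(ev$codons)
    # residues wholly inside the exon, counted from its 3' coding end
    exon_end_codon <- min(floor(bounds[ev$exon + 1] / 3), length(gi$aa))
    exon_start_codon <- floor(bounds[ev$exon] / 3) + 1L
    if (n < 0) {
      if (exon_end_codon + n < exon_start_codon)
        stop("codon_indel: deletion exceeds exon")
      drop <- (exon_end_codon + n + 1L):exon_end_codon
      gi$aa <- gi$aa[-drop]; gi$codons <- gi$codons[-drop]
      gi$sites <- gi$sites[-drop]
    } else if (n > 0) {
      ins_aa <- sample(aa_alphabet(), n, replace = TRUE)
      at <- exon_end_codon
      base <- gi$sites[at]
      nxt <- if (at < length(gi$sites)) gi$sites[at + 1] else base + 1
      new_sites <- base + seq_len(n) * (nxt - base) / (n + 1)
      gi$aa <- append(gi$aa, ins_aa, after = at)
      gi$codons <- append(gi$codons, sample_codons(ins_aa, syn), after = at)
      gi$sites <- append(gi$sites, new_sites, after = at)
    }
    if (n != 0) {
      shift <- 3L * n
      later <- gi$introns$offset > bounds[ev$exon + 1]
      gi$introns$offset[later] <- gi$introns$offset[later] + shift
      if (ev$exon < length(bounds) - 1)  # the edited exon's own 3' boundary moves
        gi$introns$offset[gi$introns$offset == bounds[ev$exon + 1]] <-
          bounds[ev$exon + 1] + shift
    }
    genes[[g]] <- gi
  } else stop("unknown scripted event type '", ev$type, "'")
  note()
  state$genes <- genes
  state
}

#' Simulate gene-family evolution along a species tree
#'
#' Evolves a focal gene family down the configured species tree: protein
#' sequences change by per-site Poisson substitutions (uniform among the 19
#' alternative residues), intron positions are inherited and modified only
#' by scripted events, duplications copy the gene together with its locus
#' neighborhood, and locus shuffles/losses rearrange flanking symbols. The
#' run is fully deterministic given `config$seed` and emits, besides the
#' per-leaf fixtures, a truth log of every applied event for end-to-end
#' validation of the inference pipeline.
#'
#' @param config A [simulation_config()].
#' @return A list of class `gene_family_simulation` with elements
#'   `config`, `truth` (events + per-leaf architectures/loci), `proteins`
#'   and `cds` (named vectors, names `copy@species`), `models` (list of
#'   [gene_model()]), `loci` (list of [locus()]), `alignment` (a
#'   [multiple_alignment()] including a `REF` row = the root protein),
#'   `species_tree`.
#' @export
simulate_gene_family <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  syn <- synonymous_codons()
  tree <- config$species_tree
  ntip <- ape::Ntip(tree)
  labels_all <- c(tree$tip.label,
                  if (!is.null(tree$node.label)) tree$node.label else
                    as.character(ntip + seq_len(tree$Nnode)))

  L <- config$root_protein_length
  root_aa <- sample(aa_alphabet(), L, replace = TRUE)
  # realistic serpin C-terminus: ER-retention tetrapeptide on the root protein
  root_aa[(L - 3):L] <- c("R", "D", "E", "L")
  root_gene <- list(
    aa = root_aa,
    codons = sample_codons(root_aa, syn),
    sites = as.numeric(seq_len(L)),
    introns = data.frame(offset = as.integer(config$root_introns$offset),
                         length = ifelse(is.na(config$root_introns$length),
                                         random_intron_length(nrow(config$root_introns)),
                                         config$root_introns$length)),
    locus_up = config$root_locus$upstream,
    locus_dn = config$root_locus$downstream,
    focal_symbol = config$root_locus$focal_gene,
    focal_present = TRUE)
  root_gene$introns$seq <-
    vapply(root_gene$introns$length, random_intron_seq, "")

  log_env <- new.env()
  log_env$events <- list()

  events_by_branch <- split(config$events,
                            vapply(config$events, `[[`, "", "branch"))

  children <- split(tree$edge[, 2], tree$edge[, 1])
  leaf_states <- list()
  evolve_all <- function(state, t) {
    state$genes <- lapply(state$genes, evolve_gene,
                          rate = config$substitution_rate, t = t, syn = syn)
    state
  }
  recurse <- function(node, state, t) {
    # scripted events are spaced evenly along the branch (event k of m at
    # fraction k/(m+1)), so consecutive duplications are separated in time
    lab <- labels_all[node]
    evs <- events_by_branch[[lab]]
    m <- length(evs)
    seg <- t / (m + 1)
    for (ev in evs) {
      state <- evolve_all(state, seg)
      state <- apply_sim_event(state, ev, syn, log_env)
    }
    state <- evolve_all(state, seg)
    if (node <= ntip) {
      leaf_states[[lab]] <<- state
      return(invisible(NULL))
    }
    for (ch in children[[as.character(node)]]) {
      tch <- tree$edge.length[which(tree$edge[, 1] == node & tree$edge[, 2] == ch)]
      recurse(ch, state, tch)
    }
  }
  root_state <- list(genes = stats::setNames(list(root_gene),
                                             config$root_gene_id))
  recurse(ntip + 1L, root_state, 0)

  # assemble outputs
  proteins <- character(0); cds <- character(0)
  models <- list(); loci <- list()
  arch <- list()
  for (sp in tree$tip.label) {
    st <- leaf_states[[sp]]
    for (g in names(st$genes)) {
      gi <- st$genes[[g]]
      nm <- paste0(g, "@", sp)
      proteins[nm] <- paste(gi$aa, collapse = "")
      cds_seq <- paste0(paste(gi$codons, collapse = ""), "TAA")
      cds[nm] <- cds_seq
      models[[nm]] <- model_from_sim_gene(gi, g, sp, cds_seq)
      if (gi$focal_present || length(c(gi$locus_up, gi$locus_dn))) {
        loci[[nm]] <- locus(species = sp, focal_gene = g,
                            upstream = gi$locus_up, downstream = gi$locus_dn,
                            focal_present = gi$focal_present)
      }
      arch[[nm]] <- list(offsets = gi$introns$offset,
                         lengths = gi$introns$length,
                         intron_seqs = gi$introns$seq,
                         locus_up = gi$locus_up, locus_dn = gi$locus_dn,
                         focal_present = gi$focal_present)
    }
  }
  aln <- alignment_from_leaf_sites(leaf_states, tree$tip.label,
                                   root_sites = as.numeric(seq_len(L)),
                                   ref_row = root_aa)
  structure(list(config = config,
                 truth = list(events = log_env$events, architectures = arch),
                 proteins = proteins, cds = cds, models = models,
                 loci = loci, alignment = aln, species_tree = tree),
            class = "gene_family_simulation")
}

# true alignment from tracked site ids (indels create fractional ids)
alignment_from_leaf_sites <- function(leaf_states, tips, root_sites, ref_row) {
  all_sites <- root_sites
  rows <- list(REF = list(sites = root_sites, aa = ref_row))
  for (sp in tips) {
    st <- leaf_states[[sp]]
    for (g in names(st$genes)) {
      gi <- st$genes[[g]]
      nm <- paste0(g, "@", sp)
      rows[[nm]] <- list(sites = gi$sites, aa = gi$aa)
      all_sites <- union(all_sites, gi$sites)
    }
  }
  all_sites <- sort(all_sites)
  gapped <- vapply(rows, function(r) {
    v <- rep("-", length(all_sites))
    v[match(r$sites, all_sites)] <- r$aa
    paste(v, collapse = "")
  }, "")
  multiple_alignment(gapped, reference_name = "REF")
}

model_from_sim_gene <- function(gi, copy_id, species, cds_seq) {
  cds_len <- nchar(cds_seq)
  offs <- gi$introns$offset
  exon_lens <- diff(c(0L, offs, cds_len))
  starts <- integer(length(exon_lens)); ends <- integer(length(exon_lens))
  pos <- 100L  # genomic offset: a 100 nt 5' flank
  for (i in seq_along(exon_lens)) {
    starts[i] <- pos
    ends[i] <- pos + exon_lens[i]
    pos <- ends[i] + if (i <= length(offs)) gi$introns$length[i] else 0L
  }
  m <- gene_model(gene_id = paste0(copy_id, "@", species), species = species,
                  seq_id = paste0(species, ".", copy_id, ".region"),
                  strand = "+", cds_exons = cbind(starts, ends))
  m
}

#' True (reconciled) gene tree of a simulated family
#'
#' Builds the gene tree implied by the scripted history: the species tree
#' with one subtree per surviving gene lineage and an internal node for each
#' scripted duplication, tips labelled `copy@species`. This is the reference
#' against which duplication-node detection on estimated gene trees is
#' judged.
#'
#' @param sim A `gene_family_simulation` (or a [simulation_config()]).
#' @return A rooted `phylo` tree with unit branch lengths.
#' @export
true_gene_tree <- function(sim) {
  config <- if (inherits(sim, "simulation_config")) sim else sim$config
  tree <- config$species_tree
  ntip <- ape::Ntip(tree)
  labels_all <- c(tree$tip.label,
                  if (!is.null(tree$node.label)) tree$node.label else
                    as.character(ntip + seq_len(tree$Nnode)))
  children <- split(tree$edge[, 2], tree$edge[, 1])
  dups_by_branch <- split(Filter(function(e) e$type == "duplication",
                                 config$events),
                          vapply(Filter(function(e) e$type == "duplication",
                                        config$events), `[[`, "", "branch"))

  split_struct <- function(struct, target, new_id) {
    if (is.character(struct)) {
      if (struct == target) return(list(struct, new_id)) else return(struct)
    }
    lapply(struct, split_struct, target = target, new_id = new_id)
  }
  render <- function(struct, node) {
    if (is.character(struct)) {
      if (node <= ntip)
        return(paste0(struct, "@", tree$tip.label[node], ":1"))
      subs <- vapply(children[[as.character(node)]],
                     function(ch) build(ch, struct), "")
      return(paste0("(", paste(subs, collapse = ","), "):1"))
    }
    paste0("(", render(struct[[1]], node), ",",
           render(struct[[2]], node), "):1")
  }
  build <- function(node, copy) {
    struct <- copy
    for (ev in dups_by_branch[[labels_all[node]]]) {
      struct <- split_struct(struct, ev$gene, ev$new_id)
    }
    render(struct, node)
  }
  nwk <- paste0(build(ntip + 1L, config$root_gene_id), ";")
  ape::read.tree(text = nwk)
}

#' Genomic sequence of a simulated gene (exons + intron sequences + flanks)
#' @param sim A `gene_family_simulation`.
#' @param name Gene name (`copy@species`).
#' @return A single DNA string.
#' @export
simulated_genomic_seq <- function(sim, name) {
  cds <- sim$cds[[name]]
  arch <- sim$truth$architectures[[name]]
  offs <- arch$offsets
  flank5 <- paste(rep("N", 100), collapse = "")
  exon_bounds <- c(0L, offs, nchar(cds))
  pieces <- character(0)
  for (i in seq_len(length(exon_bounds) - 1)) {
    pieces <- c(pieces, substr(cds, exon_bounds[i] + 1, exon_bounds[i + 1]))
    if (i <= length(offs)) pieces <- c(pieces, arch$intron_seqs[i])
  }
  paste0(flank5, paste(pieces, collapse = ""))
}

#' Write simulation fixtures to a directory
#'
#' Emits proteins.faa, cds.fna, alignment.faa, one GFF3 per species,
#' loci.tsv, species_tree.nwk, truth_log.json and a manifest.
#'
#' @param sim A `gene_family_simulation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$proteins, file.path(dir, "proteins.faa"))
  write_fasta(sim$cds, file.path(dir, "cds.fna"))
  write_fasta(sim$alignment, file.path(dir, "alignment.faa"))
  ape::write.tree(sim$species_tree, file.path(dir, "species_tree.nwk"))
  for (sp in sim$species_tree$tip.label) {
    mods <- sim$models[grepl(paste0("@", sp, "$"), names(sim$models))]
    if (length(mods))
      write_gff3(mods, file.path(dir, paste0(sp, ".gff3")))
  }
  if (length(sim$loci)) write_locus_tsv(sim$loci, file.path(dir, "loci.tsv"))
  jsonlite::write_json(
    list(seed = sim$config$seed,
         substitution_rate = sim$config$substitution_rate,
         events = sim$truth$events,
         architectures = sim$truth$architectures),
    file.path(dir, "truth_log.json"), auto_unbox = TRUE, digits = NA)
  files <- setdiff(list.files(dir), "manifest.json")
  jsonlite::write_json(
    list(tool = "introscape", seed = sim$config$seed,
         files = as.list(stats::setNames(
           unname(tools::md5sum(file.path(dir, files))), files))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @export
print.gene_family_simulation <- function(x, ...) {
  cat(sprintf("<gene_family_simulation> %d species, %d gene copies, %d scripted events (seed %d)\n",
              ape::Ntip(x$species_tree), length(x$proteins),
              length(x$truth$events), x$config$seed))
  invisible(x)
}
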