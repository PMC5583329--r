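#' Construct a gene model
#'
#' A `gene_model` holds the CDS exon structure of one protein-coding gene on a
#' genomic sequence. Coordinates are internally 0-based half-open and exons are
#' stored in transcription order (for minus-strand genes the genomically last
#' exon comes first), so all downstream architecture logic is strand-free.
#'
#' @param gene_id Gene identifier.
#' @param species Species name (free text, may be `NA`).
#' @param seq_id Identifier of the genomic sequence the gene lies on.
#' @param strand `"+"` or `"-"`.
#' @param cds_exons Two-column integer matrix of `(start, end)` genomic
#'   intervals, 0-based half-open, ordered 5' to 3' in transcription order.
#' @param partial Logical; `TRUE` for gene models known to be incomplete
#'   (e.g. truncated by assembly gaps). Partial models are exempt from the
#'   CDS-multiple-of-3 requirement.
#' @param utr5 Optional length (nt) of 5' UTR contained in the first exon,
#'   recorded but not part of the coding architecture.
#' @param check Validate hard structural invariants (ordering, non-overlap).
#'   Set to `FALSE` only to build deliberately malformed models for
#'   [validate_gene_model()].
#'
#' @return An object of class `gene_model`.
#' @seealso [introns_of()], [validate_gene_model()], [read_gff3()]
#' @export
gene_model <- function(gene_id, species = NA_character_, seq_id = "seq1",
                       strand = c("+", "-"), cds_exons, partial = FALSE,
                       utr5 = 0L, check = TRUE) {
  strand <- match.arg(strand)
  cds_exons <- matrix(as.numeric(cds_exons), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
  m <- structure(
    list(gene_id = as.character(gene_id), species = as.character(species),
         seq_id = as.character(seq_id), strand = strand,
         cds_exons = cds_exons, partial = isTRUE(partial),
         utr5 = as.integer(utr5)),
    class = "gene_model")
  if (check) {
    if (any(cds_exons[, 2] <= cds_exons[, 1]))
      stop("gene model '", gene_id, "': empty or inverted exon interval")
    if (nrow(cds_exons) > 1) {
      gaps <- exon_gaps(m)
      if (any(gaps < 0))
        stop("gene model '", gene_id,
             "': exons overlap or are not in transcription order")
    }
  }
  m
}

#' @export
print.gene_model <- function(x, ...) {
  n <- nrow(x$cds_exons)
  cat(sprintf("<gene_model> %s (%s) on %s [%s], %de/%di, CDS %d nt%s\n",
              x$gene_id, x$species, x$seq_id, x$strand, n, n - 1L,
              cds_length(x), if (x$partial) ", partial" else ""))
  invisible(x)
}

#' Exon coding lengths of a gene model, in transcription order
#' @param model A `gene_model`.
#' @return Integer vector of exon lengths (nt).
#' @export
exon_lengths <- function(model) {
  as.integer(model$cds_exons[, 2] - model$cds_exons[, 1])
}

#' Total CDS length of a gene model
#' @param model A `gene_model`.
#' @return Total coding length in nucleotides.
#' @export
cds_length <- function(model) sum(exon_lengths(model))

# genomic gaps (intron lengths) between consecutive exons, transcription order
exon_gaps <- function(model) {
  e <- model$cds_exons
  if (nrow(e) < 2) return(integer(0))
  n <- nrow(e)
  if (model$strand == "+") {
    as.integer(e[-1, 1] - e[-n, 2])
  } else {
    as.integer(e[-n, 1] - e[-1, 2])
  }
}

#' Is a gene model complete?
#'
#' Complete means not flagged partial and CDS length a positive multiple of 3.
#' @param model A `gene_model`.
#' @return Logical.
#' @export
is_complete <- function(model) {
  !model$partial && cds_length(model) > 0 && cds_length(model) %% 3 == 0
}

#' Intron records of a gene model
#'
#' For the intron between exons i and i+1, `coding_offset` is the number of
#' coding nucleotides 5' of the intron (the prefix sum of exon lengths) and
#' `length` is the genomic gap between the two exons.
#'
#' @param model A `gene_model` (single-exon models yield an empty table).
#' @return A data.frame with columns `gene_id`, `index` (1-based, 5' to 3'),
#'   `coding_offset`, `length`.
#' @export
introns_of <- function(model) {
  lens <- exon_lengths(model)
  n <- length(lens)
  if (n < 2) {
    return(data.frame(gene_id = character(0), index = integer(0),
                      coding_offset = integer(0), length = integer(0)))
  }
  gaps <- exon_gaps(model)
  if (any(gaps == 0))
    stop("gene model '", model$gene_id,
         "': zero-length intron (adjacent CDS exons)")
  data.frame(gene_id = model$gene_id, index = seq_len(n - 1L),
             coding_offset = as.integer(cumsum(lens)[-n]),
             length = gaps)
}

#' Structural diagnostics for a gene model
#'
#' Returns machine-readable diagnostics instead of raising, so that dubious
#' models (e.g. genes interrupted by sequencing errors) can be surveyed and
#' flagged rather than dropped. Models flagged `partial` are exempt from the
#' completeness checks and receive at most informational notes.
#'
#' @param model A `gene_model` (possibly built with `check = FALSE`).
#' @return A data.frame with columns `code` and `message`; zero rows when the
#'   model is structurally clean.
#' @export
validate_gene_model <- function(model) {
  codes <- character(0); msgs <- character(0)
  add <- function(code, msg) {
    codes <<- c(codes, code); msgs <<- c(msgs, msg)
  }
  lens <- exon_lengths(model)
  if (any(lens <= 0))
    add("empty_exon", "exon with non-positive length")
  if (nrow(model$cds_exons) > 1) {
    gaps <- exon_gaps(model)
    if (any(gaps < 0))
      add("unordered_exons", "exons overlap or violate transcription order")
    if (any(gaps == 0))
      add("zero_length_intron", "adjacent exons imply a zero-length intron")
  }
  if (!model$partial && sum(lens) %% 3 != 0)
    add("cds_not_multiple_of_3",
        sprintf("CDS length %d is not a multiple of 3", sum(lens)))
  if (model$partial)
    add("info_partial", "model is flagged partial; completeness not assessed")
  data.frame(code = codes, message = msgs)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features (1-based inclusive coordinates per the GFF3
#' standard) into [gene_model()] objects in internal 0-based half-open
#' coordinates, normalized to transcription order. When a gene carries several
#' transcripts, the longest complete CDS is kept (ties broken by transcript ID,
#' lexicographically). A `partial=true` attribute on the mRNA or gene marks the
#' model partial; a `species` attribute, if present, is carried over.
#'
#' @param path Path to a GFF3 file.
#' @param species Default species assigned to models lacking a `species`
#'   attribute.
#' @return A named list of `gene_model` objects (names = gene IDs).
#' @export
read_gff3 <- function(path, species = NA_character_) {
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_, "")
  } else rep(NA_character_, length(gr))

  is_cds <- type == "CDS"
  if (!any(is_cds)) stop("no CDS features in ", path)
  if (anyNA(parents[is_cds]))
    stop("CDS feature without Parent attribute in ", path)

  is_mrna <- type %in% c("mRNA", "transcript")
  tx2gene <- stats::setNames(parents[is_mrna], ids[is_mrna])
  tx_partial <- if ("partial" %in% names(md)) {
    stats::setNames(tolower(as.character(md$partial[is_mrna])) %in% "true",
                    ids[is_mrna])
  } else stats::setNames(rep(FALSE, sum(is_mrna)), ids[is_mrna])

  gene_species <- stats::setNames(rep(species, sum(type == "gene")),
                                  ids[type == "gene"])
  if ("species" %in% names(md)) {
    sp <- as.character(md$species[type == "gene"])
    gene_species[!is.na(sp)] <- sp[!is.na(sp)]
  }

  cds <- gr[is_cds]
  cds_parent <- parents[is_cds]
  models <- list()
  for (tx in sort(unique(cds_parent))) {
    if (!tx %in% names(tx2gene))
      stop("CDS parent '", tx, "' has no mRNA/transcript feature in ", path)
    sub <- cds[cds_parent == tx]
    sub <- sub[order(GenomicRanges::start(sub))]
    s0 <- GenomicRanges::start(sub) - 1L   # to 0-based half-open
    e0 <- GenomicRanges::end(sub)
    if (length(sub) > 1 && any(s0[-1] < e0[-length(e0)]))
      stop("overlapping CDS features within transcript '", tx, "'")
    strand <- as.character(GenomicRanges::strand(sub))[1]
    if (!strand %in% c("+", "-"))
      stop("transcript '", tx, "' lacks a strand")
    ex <- cbind(s0, e0)
    if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
    gid <- tx2gene[[tx]]
    m <- gene_model(gene_id = gid,
                    species = if (gid %in% names(gene_species)) gene_species[[gid]] else species,
                    seq_id = as.character(GenomicRanges::seqnames(sub))[1],
                    strand = strand, cds_exons = ex,
                    partial = isTRUE(tx_partial[[tx]]))
    m$transcript_id <- tx
    # keep the best transcript per gene: complete first, then longest,
    # then lexicographically smallest transcript ID
    old <- models[[gid]]
    if (is.null(old) || better_transcript(m, old)) models[[gid]] <- m
  }
  models[order(names(models))]
}

better_transcript <- function(new, old) {
  key <- function(m) c(is_complete(m), cds_length(m))
  kn <- key(new); ko <- key(old)
  if (kn[1] != ko[1]) return(kn[1] > ko[1])
  if (kn[2] != ko[2]) return(kn[2] > ko[2])
  new$transcript_id < old$transcript_id
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/CDS features per model, converting back to 1-based
#' inclusive coordinates. Round-trips with [read_gff3()] up to feature
#' ordering.
#'
#' @param models A `gene_model` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  if (inherits(models, "gene_model")) models <- list(models)
  rows <- lapply(models, function(m) {
    ex <- m$cds_exons
    span <- range(c(ex[, 1], ex[, 2]))
    tx <- if (!is.null(m$transcript_id)) m$transcript_id else paste0(m$gene_id, ".t1")
    gene_attr <- paste0("ID=", m$gene_id,
                        if (!is.na(m$species)) paste0(";species=", m$species) else "")
    mrna_attr <- paste0("ID=", tx, ";Parent=", m$gene_id,
                        if (m$partial) ";partial=true" else "")
    lines <- c(
      paste(m$seq_id, "introscape", "gene", span[1] + 1L, span[2], ".",
            m$strand, ".", gene_attr, sep = "\t"),
      paste(m$seq_id, "introscape", "mRNA", span[1] + 1L, span[2], ".",
            m$strand, ".", mrna_attr, sep = "\t"))
    ord <- order(ex[, 1])
    for (i in ord) {
      lines <- c(lines, paste(m$seq_id, "introscape", "CDS",
                              ex[i, 1] + 1L, ex[i, 2], ".", m$strand, "0",
                              paste0("ID=cds-", tx, ";Parent=", tx), sep = "\t"))
    }
    lines
  })
  writeLines(c("##gff-version 3", unlist(rows)), path)
  invisible(path)
}

#' Construct a multiple protein alignment with a designated reference row
#'
#' @param rows Named character vector of equal-length gapped sequences
#'   (gap character `-`).
#' @param reference_name Name of the row used as the numbering standard
#'   (in serpin work, mature human alpha-1-antitrypsin).
#' @return An object of class `multiple_alignment`.
#' @export
multiple_alignment <- function(rows, reference_name) {
  rows <- vapply(rows, toupper, "")
  if (is.null(names(rows)) || anyNA(names(rows)) || any(names(rows) == ""))
    stop("alignment rows must be named")
  if (anyDuplicated(names(rows))) stop("duplicate sequence names in alignment")
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows differ in length")
  if (!reference_name %in% names(rows))
    stop("reference '", reference_name, "' not found in alignment")
  structure(list(rows = rows, reference_name = reference_name),
            class = "multiple_alignment")
}

#' @export
print.multiple_alignment <- function(x, ...) {
  cat(sprintf("<multiple_alignment> %d sequences x %d columns (reference: %s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$reference_name))
  invisible(x)
}

#' Remove gaps from aligned sequences
#' @param x Character vector of gapped sequences.
#' @return Ungapped sequences.
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)

#' Read an aligned FASTA file into a `multiple_alignment`
#' @param path Aligned FASTA path.
#' @param reference_name Name of the reference row.
#' @return A `multiple_alignment`.
#' @export
read_alignment <- function(path, reference_name) {
  ss <- Biostrings::readAAStringSet(path)
  multiple_alignment(stats::setNames(as.character(ss), names(ss)),
                     reference_name)
}

#' Write sequences to FASTA (wrapped at 60 columns)
#' @param seqs Named character vector (protein or nucleotide), or a
#'   `multiple_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "multiple_alignment")) seqs <- seqs$rows
  ss <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Node ages of an ultrametric tree
#'
#' Ages are measured back from the leaves (leaves at age 0), in the units of
#' the branch lengths (MY for time-calibrated trees).
#'
#' @param tree An ultrametric `phylo` tree.
#' @param tol Relative tolerance for the ultrametricity check.
#' @return Numeric vector of ages indexed by node number (tips then internal
#'   nodes, `ape` convention).
#' @export
node_ages <- function(tree, tol = 1e-6) {
  if (!ape::is.ultrametric(tree, tol = tol))
    stop("tree is not ultrametric; node ages are undefined")
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  ages[seq_len(ape::Ntip(tree))] <- 0
  ages
}
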