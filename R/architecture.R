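#' Architecture profile of a gene
#'
#' Summarizes a gene's exon/intron architecture: the set of reference-numbered
#' intron labels, the pattern string (`"4e/3i"`, `"6e/5i"`, ...), and exon and
#' intron sizes in transcription order.
#'
#' @param model A [gene_model()].
#' @param labels Label table for this gene from [label_introns()] (may have
#'   zero rows for single-exon genes).
#' @return An object of class `architecture_profile`.
#' @export
architecture_profile <- function(model, labels) {
  lens <- exon_lengths(model)
  n <- length(lens)
  if (nrow(labels) != n - 1L)
    stop("label table does not match the model's intron count")
  structure(
    list(gene_id = model$gene_id, species = model$species,
         labels = labels$label, mappable = labels$mappable,
         pattern = sprintf("%de/%di", n, n - 1L),
         exon_sizes = lens, intron_sizes = labels$intron_length,
         partial = model$partial),
    class = "architecture_profile")
}

#' @export
print.architecture_profile <- function(x, ...) {
  cat(sprintf("<architecture_profile> %s: %s, introns [%s]%s\n",
              x$gene_id, x$pattern, paste(x$labels, collapse = ", "),
              if (x$partial) " (partial)" else ""))
  invisible(x)
}

#' Exon count encoded in a pattern string
#' @param pattern A pattern string such as `"4e/3i"`.
#' @return Integer exon count.
#' @export
pattern_exons <- function(pattern) {
  as.integer(sub("e/.*$", "", pattern))
}

#' Compare architecture profiles against an ancestral intron set
#'
#' Builds a presence/absence/unknown matrix of genes x intron labels and calls
#' per-gene gains (labels outside the ancestral reference set) and losses
#' (reference labels absent from a *complete* gene). Partial genes can never
#' be scored for loss: an intron missing from an incomplete model is recorded
#' as unknown, mirroring how genes truncated by sequencing errors must be
#' treated.
#'
#' Labels are exact markers: two introns are "the same" only when codon number
#' and phase letter agree after projection. Near-misses (within one codon,
#' same phase) are kept distinct and listed in the `proximity_warnings`
#' attribute rather than merged.
#'
#' @param profiles List of [architecture_profile()] objects.
#' @param reference_labels Character vector of ancestral intron labels
#'   (for vertebrate serpins, `c("192a","225a","300c")`).
#' @return An object of class `gain_loss_matrix`: a list with `matrix`
#'   (values `"P"`/`"A"`/`"U"`), `conserved_labels`, `novel_labels`, and
#'   per-gene `gains` and `losses`.
#' @export
compare_architectures <- function(profiles,
                                  reference_labels = c("192a", "225a", "300c")) {
  if (length(profiles) < 1) stop("need at least one profile")
  ids <- vapply(profiles, `[[`, "", "gene_id")
  if (anyDuplicated(ids)) stop("duplicate gene_ids: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  all_labels <- unique(c(reference_labels,
                         unlist(lapply(profiles, `[[`, "labels"))))
  parsed <- parse_intron_label(all_labels)
  ord <- order(parsed$codon, parsed$phase)
  all_labels <- all_labels[ord]

  m <- matrix("A", nrow = length(profiles), ncol = length(all_labels),
              dimnames = list(ids, all_labels))
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    m[i, intersect(p$labels, all_labels)] <- "P"
    if (p$partial) m[i, setdiff(all_labels, p$labels)] <- "U"
  }
  gains <- lapply(profiles, function(p) setdiff(p$labels, reference_labels))
  losses <- lapply(profiles, function(p) {
    if (p$partial) character(0) else setdiff(reference_labels, p$labels)
  })
  names(gains) <- names(losses) <- ids

  # proximity warnings: distinct labels within one codon, same phase
  pp <- parse_intron_label(all_labels)
  warn <- character(0)
  if (nrow(pp) > 1) {
    for (i in seq_len(nrow(pp) - 1)) {
      j <- i + 1L
      if (pp$phase[i] == pp$phase[j] && abs(pp$codon[j] - pp$codon[i]) == 1)
        warn <- c(warn, sprintf("labels %s and %s differ by one codon; kept distinct",
                                pp$label[i], pp$label[j]))
    }
  }
  structure(list(matrix = m,
                 conserved_labels = intersect(all_labels, reference_labels),
                 novel_labels = setdiff(all_labels, reference_labels),
                 gains = gains, losses = losses,
                 proximity_warnings = warn),
            class = "gain_loss_matrix")
}

#' @export
print.gain_loss_matrix <- function(x, ...) {
  cat("<gain_loss_matrix>", nrow(x$matrix), "genes x", ncol(x$matrix), "labels\n")
  print(x$matrix)
  invisible(x)
}

#' Presence map for one intron label across species
#'
#' Convenience extractor for Dollo inference: converts one column of a
#' [compare_architectures()] matrix into a named presence vector
#' (1 = present, 0 = absent, NA = unknown) keyed by species.
#'
#' @param glm A `gain_loss_matrix`.
#' @param label Intron label (column name).
#' @param species Named character vector mapping gene_id to species; defaults
#'   to gene_ids themselves.
#' @return Named numeric vector over species.
#' @export
presence_of_label <- function(glm, label, species = NULL) {
  col <- glm$matrix[, label]
  v <- ifelse(col == "P", 1, ifelse(col == "A", 0, NA))
  if (!is.null(species)) names(v) <- species[names(v)]
  v
}

#' Insert an intron into a gene model
#'
#' Splits the exon containing `coding_offset` (which must lie strictly inside
#' an exon, not at an existing junction) and shifts everything downstream in
#' transcription by the new intron's length. The encoded CDS is unchanged:
#' intron insertion is purely an architectural event.
#'
#' @param model A [gene_model()].
#' @param coding_offset Coding nucleotides 5' of the new intron.
#' @param intron_length Length (nt) of the inserted intron (>= 1).
#' @return A new `gene_model` with one more exon.
#' @export
insert_intron <- function(model, coding_offset, intron_length) {
  if (intron_length < 1) stop("intron length must be >= 1")
  lens <- exon_lengths(model)
  bounds <- c(0L, cumsum(lens))
  if (coding_offset %in% bounds)
    stop("coding offset ", coding_offset,
         " is at an exon junction or CDS boundary; insertion must fall strictly inside an exon")
  if (coding_offset < 0 || coding_offset > sum(lens))
    stop("coding offset outside the CDS")
  k <- findInterval(coding_offset, bounds)     # exon to split (1-based)
  within <- coding_offset - bounds[k]          # nt of exon k 5' of new intron
  ex <- model$cds_exons
  L <- as.integer(intron_length)
  if (model$strand == "+") {
    e1 <- c(ex[k, 1], ex[k, 1] + within)
    e2 <- c(ex[k, 1] + within + L, ex[k, 2] + L)
    if (k < nrow(ex)) ex[(k + 1):nrow(ex), ] <- ex[(k + 1):nrow(ex), ] + L
    ex <- rbind(ex[seq_len(k - 1), , drop = FALSE], e1, e2,
                ex[seq_len(nrow(ex))[-seq_len(k)], , drop = FALSE])
  } else {
    e1 <- c(ex[k, 2] - within, ex[k, 2])
    e2 <- c(ex[k, 1] - L, ex[k, 2] - within - L)
    if (k < nrow(ex)) ex[(k + 1):nrow(ex), ] <- ex[(k + 1):nrow(ex), ] - L
    ex <- rbind(ex[seq_len(k - 1), , drop = FALSE], e1, e2,
                ex[seq_len(nrow(ex))[-seq_len(k)], , drop = FALSE])
  }
  rownames(ex) <- NULL
  out <- model
  out$cds_exons <- ex
  # shifting may push minus-strand coordinates below zero; renormalize
  shift <- min(ex[, 1])
  if (shift < 0) out$cds_exons <- ex - shift
  out
}

#' Apply a codon-level insertion or deletion to one exon
#'
#' Changes the coding length of exon `exon_index` by `3 * codons` at its 3'
#' end, keeping all intron lengths constant, so the CDS stays a multiple of 3.
#' Used to model size differences like a terminal serpin exon of 306 bp
#' (one codon more than the conserved 303 bp).
#'
#' @param model A [gene_model()].
#' @param exon_index Exon to resize (1-based, transcription order).
#' @param codons Signed number of codons to add (positive) or remove
#'   (negative).
#' @return A new `gene_model`.
#' @export
apply_codon_indel <- function(model, exon_index, codons) {
  lens <- exon_lengths(model)
  if (exon_index < 1 || exon_index > length(lens)) stop("no such exon")
  d <- 3L * as.integer(codons)
  if (d == 0) return(model)
  if (d < 0 && -d >= lens[exon_index])
    stop("deletion of ", -codons, " codons exceeds exon ", exon_index,
         " (", lens[exon_index], " nt)")
  ex <- model$cds_exons
  n <- nrow(ex)
  if (model$strand == "+") {
    ex[exon_index, 2] <- ex[exon_index, 2] + d
    if (exon_index < n)
      ex[(exon_index + 1):n, ] <- ex[(exon_index + 1):n, ] + d
  } else {
    ex[exon_index, 1] <- ex[exon_index, 1] - d
    if (exon_index < n)
      ex[(exon_index + 1):n, ] <- ex[(exon_index + 1):n, ] - d
  }
  out <- model
  out$cds_exons <- ex
  shift <- min(ex[, 1])
  if (shift < 0) out$cds_exons <- ex - shift
  out
}

#' Exon/intron size table across genes
#'
#' Aligns architectures on the union of intron labels (sorted by codon and
#' phase) and reports, per position, each gene's size plus the min-max range.
#' Exon slots are defined between consecutive labels of the union ordering;
#' a gene contributes an exon size to a slot only when its own consecutive
#' introns delimit exactly that slot (genes lacking a position are blank, NA).
#'
#' @param profiles List of [architecture_profile()] objects.
#' @return A list with data.frames `introns` and `exons`; each has one row
#'   per gene and per-position columns, plus `min`/`max` summary rows stored
#'   in the `range` attribute.
#' @export
size_table <- function(profiles) {
  if (length(profiles) == 0)
    return(list(introns = data.frame(), exons = data.frame()))
  all_labels <- unique(unlist(lapply(profiles, `[[`, "labels")))
  if (length(all_labels)) {
    p <- parse_intron_label(all_labels)
    all_labels <- all_labels[order(p$codon, p$phase)]
  }
  ids <- vapply(profiles, `[[`, "", "gene_id")

  introns <- matrix(NA_integer_, length(profiles), length(all_labels),
                    dimnames = list(ids, all_labels))
  # exon slots: before first label, between consecutive labels, after last
  slots <- c("e[start]",
             if (length(all_labels) > 1)
               paste0("e[", all_labels[-length(all_labels)], ":",
                      all_labels[-1], "]"),
             if (length(all_labels)) "e[end]")
  if (length(all_labels) == 0) slots <- "e[start]"
  exons <- matrix(NA_integer_, length(profiles), length(slots),
                  dimnames = list(ids, slots))
  for (i in seq_along(profiles)) {
    pr <- profiles[[i]]
    introns[i, pr$labels] <- pr$intron_sizes
    nl <- length(pr$labels)
    if (nl == 0) { exons[i, "e[start]"] <- pr$exon_sizes[1]; next }
    exons[i, "e[start]"] <- pr$exon_sizes[1]
    exons[i, "e[end]"] <- pr$exon_sizes[nl + 1]
    if (nl > 1) {
      for (k in seq_len(nl - 1)) {
        slot <- paste0("e[", pr$labels[k], ":", pr$labels[k + 1], "]")
        if (slot %in% slots) exons[i, slot] <- pr$exon_sizes[k + 1]
      }
    }
  }
  rng <- function(m) {
    data.frame(position = colnames(m),
               min = suppressWarnings(apply(m, 2, min, na.rm = TRUE)),
               max = suppressWarnings(apply(m, 2, max, na.rm = TRUE)),
               row.names = NULL)
  }
  out <- list(introns = as.data.frame(introns), exons = as.data.frame(exons))
  attr(out, "range") <- list(introns = rng(introns), exons = rng(exons))
  out
}

#' Write a gain/loss matrix to TSV
#' @param glm A `gain_loss_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gain_loss_tsv <- function(glm, path) {
  df <- data.frame(gene_id = rownames(glm$matrix), glm$matrix,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
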