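#' Per-column conservation profile of an alignment
#'
#' For each column, the modal residue is the most frequent amino acid (gaps
#' never count as the mode but do count in the denominator, so a gappy column
#' scores low), and the modal fraction is binned GENEDOC-style into
#' 90-100, 70-89, 50-69 and <50 percent classes on integer-rounded values.
#'
#' @param aln A [multiple_alignment()] or named character vector of rows
#'   (>= 2 sequences).
#' @return A list of class `conservation_profile`: `columns` (data.frame with
#'   `column`, `modal_residue`, `modal_pct`, `bin`) and `totals` (named count
#'   per bin, summing to the alignment length).
#' @export
conservation_profile <- function(aln) {
  rows <- if (inherits(aln, "multiple_alignment")) aln$rows else aln
  if (length(rows) < 2) stop("conservation needs at least 2 sequences")
  mat <- do.call(rbind, strsplit(toupper(rows), ""))
  nseq <- nrow(mat); ncol_ <- ncol(mat)
  modal_res <- character(ncol_); modal_pct <- numeric(ncol_)
  for (j in seq_len(ncol_)) {
    col <- mat[, j]
    col <- col[col != "-"]
    if (length(col) == 0) {
      modal_res[j] <- NA_character_; modal_pct[j] <- 0
    } else {
      tab <- sort(table(col), decreasing = TRUE)
      modal_res[j] <- names(tab)[1]
      modal_pct[j] <- 100 * tab[[1]] / nseq
    }
  }
  rp <- round(modal_pct)
  bin <- ifelse(rp >= 90, "90-100",
                ifelse(rp >= 70, "70-89",
                       ifelse(rp >= 50, "50-69", "<50")))
  bins <- factor(bin, levels = c("90-100", "70-89", "50-69", "<50"))
  structure(list(columns = data.frame(column = seq_len(ncol_),
                                      modal_residue = modal_res,
                                      modal_pct = modal_pct, bin = bin),
                 totals = table(bins)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("<conservation_profile>", nrow(x$columns), "columns; bins:",
      paste(names(x$totals), as.integer(x$totals), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Canonical-residue checklist across an alignment
#'
#' Scores a list of canonical serpin positions (reference codon number +
#' expected residue, in the tradition of the Irving consensus set) against
#' the alignment: a position is `conserved` when the canonical residue
#' occurs in at least half of the sequences at its projected column,
#' `partial` when present in fewer than half but more than none, `missing`
#' when absent everywhere. Positions beyond the reference are reported
#' `unmappable` and excluded from the counts.
#'
#' @param aln A [multiple_alignment()].
#' @param canonical Data.frame with columns `ref_codon` and `residue`.
#' @return A list of class `checklist_result`: `positions` data.frame and
#'   `counts` per status.
#' @export
residue_checklist <- function(aln, canonical) {
  stopifnot(inherits(aln, "multiple_alignment"))
  ref <- strsplit(aln$rows[[aln$reference_name]], "")[[1]]
  ref_res_no <- cumsum(ref != "-")
  mat <- do.call(rbind, strsplit(toupper(aln$rows), ""))
  nseq <- nrow(mat)
  status <- character(nrow(canonical)); freq <- numeric(nrow(canonical))
  for (i in seq_len(nrow(canonical))) {
    n <- canonical$ref_codon[i]
    if (n < 1 || n > max(ref_res_no)) {
      status[i] <- "unmappable"; freq[i] <- NA_real_; next
    }
    col <- match(n, ref_res_no)
    f <- sum(mat[, col] == toupper(canonical$residue[i])) / nseq
    freq[i] <- f
    status[i] <- if (f >= 0.5) "conserved" else if (f > 0) "partial" else "missing"
  }
  pos <- data.frame(ref_codon = canonical$ref_codon,
                    residue = canonical$residue,
                    frequency = freq, status = status)
  counts <- table(factor(status,
                         levels = c("conserved", "partial", "missing", "unmappable")))
  structure(list(positions = pos, counts = counts), class = "checklist_result")
}

#' @export
print.checklist_result <- function(x, ...) {
  cat("<checklist_result>",
      paste(names(x$counts), as.integer(x$counts), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Annotate reactive-center loops across an alignment
#'
#' P-site columns are anchored on the reference row: P1 is the supplied
#' column, P2..P17 are the columns of the preceding reference residues and
#' P1' the column of the next one. Per protein, the RCL is the degapped
#' P17-P1' subsequence; the hinge (P15-P9) is classified inhibitory-
#' consistent when at least 75% of its residues are small (G/A/S/T/V) — the
#' standard serpin-literature criterion; collagen-chaperone serpins fail it.
#' Gaps at P5-P6 (a divergent-paralog signature) are flagged, and the
#' C-terminal ER-retention variant is reported.
#'
#' @param aln A [multiple_alignment()].
#' @param p1_column Alignment column of the reference's P1 residue.
#' @param small_residues Residues counted as hinge-compatible.
#' @param hinge_threshold Fraction of small hinge residues required for an
#'   inhibitory-consistent call.
#' @return Data.frame with one row per protein: `name`, `rcl`, `hinge`,
#'   `inhibitory` (NA when truncated), `truncated`, `gaps_P5_P6`,
#'   `er_retention`.
#' @export
rcl_annotate <- function(aln, p1_column,
                         small_residues = c("G", "A", "S", "T", "V"),
                         hinge_threshold = 0.75) {
  stopifnot(inherits(aln, "multiple_alignment"))
  ref <- strsplit(aln$rows[[aln$reference_name]], "")[[1]]
  if (p1_column < 1 || p1_column > length(ref)) stop("P1 column out of range")
  if (ref[p1_column] == "-") stop("reference has a gap at the P1 column")
  res_cols <- which(ref != "-")
  i1 <- match(p1_column, res_cols)
  if (is.na(i1)) stop("P1 column is not a reference residue column")
  if (i1 < 17) stop("fewer than 17 reference residues upstream of P1")
  # site columns: P17..P1 then P1'
  p_cols <- res_cols[(i1 - 16):i1]
  p1p_col <- if (i1 < length(res_cols)) res_cols[i1 + 1] else NA_integer_
  site_names <- c(paste0("P", 17:1), "P1p")
  cols <- c(p_cols, p1p_col)

  out <- lapply(names(aln$rows), function(nm) {
    v <- strsplit(aln$rows[[nm]], "")[[1]]
    sites <- ifelse(is.na(cols), "-", v[cols])
    names(sites) <- site_names
    rcl <- paste(sites[sites != "-"], collapse = "")
    hinge_sites <- sites[paste0("P", 15:9)]
    hinge <- paste(hinge_sites[hinge_sites != "-"], collapse = "")
    n_upstream <- sum(v[seq_len(p1_column - 1)] != "-")
    truncated <- n_upstream < 9
    inhibitory <- if (truncated || nchar(hinge) == 0) NA else
      mean(strsplit(hinge, "")[[1]] %in% small_residues) >= hinge_threshold
    if (truncated)
      warning("truncated RCL for '", nm, "': fewer than 9 residues upstream of P1")
    data.frame(name = nm, rcl = rcl, hinge = hinge,
               inhibitory = inhibitory, truncated = truncated,
               gaps_P5_P6 = any(sites[c("P5", "P6")] == "-"),
               er_retention = er_retention(degap(aln$rows[[nm]])))
  })
  do.call(rbind, out)
}

#' C-terminal ER-retention signal
#'
#' Scans the final four residues of each protein for the canonical
#' endoplasmic-reticulum retention tetrapeptide `[RKH]DEL` and returns the
#' variant found (RDEL/KDEL/HDEL) or NA.
#'
#' @param protein Character vector of (ungapped) protein sequences.
#' @return Character vector: the matching 4-mer, or `NA` where absent.
#' @export
er_retention <- function(protein) {
  protein <- toupper(protein)
  tail4 <- substring(protein, pmax(nchar(protein) - 3, 1), nchar(protein))
  ifelse(nchar(protein) >= 4 & grepl("^[RKH]DEL$", tail4), tail4, NA_character_)
}

#' Percent identity between two aligned rows
#'
#' Identical residue pairs over columns where both rows carry a residue
#' (single- and dual-gap columns excluded), times 100, rounded to the
#' integer percentages usually reported.
#'
#' @param a,b Equal-length aligned rows.
#' @param digits Rounding digits (0 = integer reporting).
#' @return Percent identity.
#' @export
percent_identity <- function(a, b, digits = 0) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) stop("rows differ in aligned length")
  keep <- va != "-" & vb != "-"
  if (!any(keep)) stop("no comparable (gap-free) columns")
  round(100 * sum(va[keep] == vb[keep]) / sum(keep), digits)
}

#' Full feature report for an alignment
#'
#' Bundles [conservation_profile()], optional [residue_checklist()], optional
#' [rcl_annotate()], and percent identity of every sequence against the
#' reference row.
#'
#' @param aln A [multiple_alignment()].
#' @param canonical Optional canonical residue table (see
#'   [residue_checklist()]).
#' @param p1_column Optional P1 alignment column (see [rcl_annotate()]).
#' @return A list of class `feature_report`.
#' @export
feature_report <- function(aln, canonical = NULL, p1_column = NULL) {
  idn <- vapply(names(aln$rows), function(nm)
    percent_identity(aln$rows[[nm]], aln$rows[[aln$reference_name]]), 0)
  structure(list(
    conservation = conservation_profile(aln),
    checklist = if (!is.null(canonical)) residue_checklist(aln, canonical),
    rcl = if (!is.null(p1_column)) rcl_annotate(aln, p1_column),
    er_retention = stats::setNames(er_retention(degap(aln$rows)),
                                   names(aln$rows)),
    identity_vs_reference = idn,
    reference_name = aln$reference_name),
    class = "feature_report")
}

#' @export
print.feature_report <- function(x, ...) {
  cat("<feature_report> vs", x$reference_name, "\n")
  print(x$conservation)
  if (!is.null(x$checklist)) print(x$checklist)
  cat("identity vs reference:",
      paste(names(x$identity_vs_reference), x$identity_vs_reference,
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}
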