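#' Codon number and phase of a coding offset
#'
#' An intron that interrupts the CDS after `c` coding nucleotides falls in (or
#' after) codon `q = ceiling(c/3)`, with `r = c - 3*(q-1)` nucleotides of that
#' codon lying 5' of the intron. The remainder `r` in `{1,2,3}` maps to the
#' phase letters a/b/c: `a` = intron after the 1st nucleotide of codon q,
#' `b` = after the 2nd, `c` = after the 3rd (i.e. between codons q and q+1).
#'
#' @param coding_offset Integer vector of coding offsets (>= 1).
#' @return A data.frame with columns `coding_offset`, `codon` (q),
#'   `remainder` (r) and `phase` (letter).
#' @export
phase_of <- function(coding_offset) {
  c_ <- as.integer(coding_offset)
  if (length(c_) == 0 || anyNA(c_) || any(c_ < 1))
    stop("coding offsets must be integers >= 1")
  q <- ceiling(c_ / 3)
  r <- c_ - 3L * (q - 1L)
  data.frame(coding_offset = c_, codon = as.integer(q), remainder = as.integer(r),
             phase = phase_convention()[r])
}

#' The a/b/c phase-letter convention
#'
#' Returns the bijection from remainder r (coding nucleotides of the
#' interrupted codon lying 5' of the intron) to phase letter: 1 = a, 2 = b,
#' 3 = c. This is the only convention family consistent with the conserved
#' serpin exon sizes (introns 192a and 225a bound a 99 bp exon: 99 = 3*33,
#' same-letter introns must be a multiple of 3 apart).
#'
#' @return Named character vector mapping remainders `"1"`, `"2"`, `"3"` to
#'   letters.
#' @export
phase_convention <- function() {
  stats::setNames(c("a", "b", "c"), 1:3)
}

#' Format / parse intron position labels such as "192a"
#'
#' @param codon Reference codon number(s).
#' @param phase Phase letter(s), one of a/b/c.
#' @return `format_intron_label`: character labels. `parse_intron_label`: a
#'   data.frame with `codon` and `phase`.
#' @export
format_intron_label <- function(codon, phase) {
  stopifnot(all(phase %in% c("a", "b", "c")))
  paste0(as.integer(codon), phase)
}

#' @rdname format_intron_label
#' @param label Character vector of labels like `"192a"`.
#' @export
parse_intron_label <- function(label) {
  ok <- grepl("^[0-9]+[abc]$", label)
  if (!all(ok)) stop("malformed intron label(s): ",
                     paste(label[!ok], collapse = ", "))
  data.frame(label = label,
             codon = as.integer(sub("[abc]$", "", label)),
             phase = sub("^[0-9]+", "", label))
}

#' Project a gene codon onto reference numbering through an alignment
#'
#' Finds the alignment column holding the q-th residue of the gene row and
#' returns the number of reference residues at or before that column. If the
#' reference carries a gap in that column the position has no exact reference
#' equivalent: the nearest preceding reference residue number is returned and
#' the position flagged unmappable rather than silently approximated.
#'
#' @param q Gene codon number(s) (1-based in the ungapped gene row).
#' @param aln A [multiple_alignment()] containing the gene and the reference.
#' @param gene_name Name of the gene row.
#' @return A data.frame with columns `gene_codon`, `ref_codon`, `mappable`.
#' @export
project_codon <- function(q, aln, gene_name) {
  stopifnot(inherits(aln, "multiple_alignment"))
  if (!gene_name %in% names(aln$rows))
    stop("gene '", gene_name, "' not in alignment")
  g <- strsplit(aln$rows[[gene_name]], "")[[1]]
  r <- strsplit(aln$rows[[aln$reference_name]], "")[[1]]
  gene_res_no <- cumsum(g != "-")
  ref_res_no <- cumsum(r != "-")
  q <- as.integer(q)
  if (any(q < 1) || any(q > max(gene_res_no)))
    stop("codon number beyond the end of gene '", gene_name, "'")
  col <- match(q, gene_res_no)   # first column reaching residue q = its column
  data.frame(gene_codon = q,
             ref_codon = as.integer(ref_res_no[col]),
             mappable = r[col] != "-")
}

#' Label the introns of a gene in reference codon numbering
#'
#' Composes [phase_of()] and [project_codon()]: each intron's coding offset
#' yields a gene codon and phase letter; the codon is projected onto the
#' reference row of the alignment, giving labels such as `"192a"`. When a CDS
#' sequence is supplied, its translation is checked against the degapped
#' alignment row for the gene before any labelling (a mismatch means the gene
#' model and the alignment disagree and every downstream label would be
#' suspect).
#'
#' @param model A complete [gene_model()].
#' @param aln A [multiple_alignment()] containing the gene row and reference.
#' @param cds Optional CDS nucleotide sequence of the model (a single string);
#'   when given, `translate(cds)` (minus the stop) must equal the degapped
#'   alignment row.
#' @param gene_name Alignment row name for this gene; defaults to the model's
#'   `gene_id`.
#' @return A data.frame with one row per intron: `gene_id`, `index`,
#'   `coding_offset`, `gene_codon`, `phase`, `ref_codon`, `label`, `mappable`,
#'   `intron_length`.
#' @export
label_introns <- function(model, aln, cds = NULL, gene_name = model$gene_id) {
  if (!gene_name %in% names(aln$rows))
    stop("gene '", gene_name, "' not in alignment")
  prot <- degap(aln$rows[[gene_name]])
  if (!is.null(cds)) {
    tr <- as.character(Biostrings::translate(
      Biostrings::DNAString(cds), no.init.codon = TRUE))
    tr <- sub("\\*$", "", tr)
    if (tr != prot)
      stop("translated CDS of '", model$gene_id,
           "' does not match its alignment row")
  } else {
    ncod <- cds_length(model) %/% 3
    if (!cds_length(model) %% 3 == 0 || !(ncod %in% c(nchar(prot), nchar(prot) + 1L)))
      stop("CDS length of '", model$gene_id,
           "' is inconsistent with its alignment row (", nchar(prot),
           " residues)")
  }
  ir <- introns_of(model)
  if (nrow(ir) == 0) {
    return(data.frame(gene_id = character(0), index = integer(0),
                      coding_offset = integer(0), gene_codon = integer(0),
                      phase = character(0), ref_codon = integer(0),
                      label = character(0), mappable = logical(0),
                      intron_length = integer(0)))
  }
  ph <- phase_of(ir$coding_offset)
  pr <- project_codon(ph$codon, aln, gene_name)
  data.frame(gene_id = ir$gene_id, index = ir$index,
             coding_offset = ir$coding_offset, gene_codon = ph$codon,
             phase = ph$phase, ref_codon = pr$ref_codon,
             label = format_intron_label(pr$ref_codon, ph$phase),
             mappable = pr$mappable, intron_length = ir$length)
}

#' Exon length between two consecutive introns
#'
#' The coding exon enclosed by two consecutive introns has length
#' `c2 - c1` (difference of coding offsets). Phase arithmetic guarantees
#' `(c2 - c1) mod 3 == (r2 - r1) mod 3`, so same-letter introns always bound
#' an exon whose length is a multiple of 3 (e.g. 192a and 225a bound the
#' conserved 99 bp serpin exon eII).
#'
#' @param labels Output of [label_introns()] (or [introns_of()]).
#' @param i,j Intron indices; must be consecutive (`j == i + 1`).
#' @return Exon length in nucleotides.
#' @export
exon_length_between <- function(labels, i, j) {
  if (j != i + 1L) stop("introns ", i, " and ", j, " are not consecutive")
  ri <- labels[labels$index == i, ]
  rj <- labels[labels$index == j, ]
  if (nrow(ri) != 1 || nrow(rj) != 1)
    stop("intron index not found (or ambiguous) in the label table")
  len <- rj$coding_offset - ri$coding_offset
  if (len <= 0) stop("coding offsets do not increase with intron index")
  # mod-3 consistency between exon length and phase letters
  r <- function(x) x$coding_offset - 3L * (ceiling(x$coding_offset / 3) - 1L)
  stopifnot(len %% 3 == (r(rj) - r(ri)) %% 3)
  as.integer(len)
}

#' Write an intron label table to TSV
#'
#' Columns: gene_id, intron_index, coding_offset, ref_label, mappable,
#' intron_length.
#'
#' @param labels Output of [label_introns()] (rows from several genes may be
#'   concatenated with `rbind`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intron_tsv <- function(labels, path) {
  out <- data.frame(gene_id = labels$gene_id, intron_index = labels$index,
                    coding_offset = labels$coding_offset,
                    ref_label = labels$label, mappable = labels$mappable,
                    intron_length = labels$intron_length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
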