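#' Construct a locus description
#'
#' A locus is the neighborhood of a focal gene described as two ordered lists
#' of flanking gene symbols, nearest first on each side. Symbols are
#' normalized to uppercase; orientation (strand signs) may be recorded but is
#' treated as annotation, not as part of the order signal.
#'
#' @param species Species name.
#' @param focal_gene Symbol of the focal gene.
#' @param upstream,downstream Character vectors of flanking symbols, nearest
#'   first.
#' @param strands Optional named character vector (`"+"`/`"-"`) over flanking
#'   symbols.
#' @param focal_present Is the focal gene itself present at the locus?
#'   `FALSE` describes a neighborhood that retained its markers but lost
#'   (or only partially retains) the focal gene.
#' @return An object of class `locus`.
#' @export
locus <- function(species, focal_gene, upstream = character(0),
                  downstream = character(0), strands = NULL,
                  focal_present = TRUE) {
  upstream <- toupper(upstream); downstream <- toupper(downstream)
  focal_gene <- toupper(focal_gene)
  if (focal_gene %in% c(upstream, downstream))
    stop("focal gene must not appear in the flank lists")
  if (anyDuplicated(c(upstream, downstream)))
    stop("duplicate symbol in flanks of ", species)
  structure(list(species = species, focal_gene = focal_gene,
                 upstream = upstream, downstream = downstream,
                 strands = strands, focal_present = isTRUE(focal_present)),
            class = "locus")
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("<locus> %s: %s | %s%s | %s\n", x$species,
              paste(rev(x$upstream), collapse = "-"),
              x$focal_gene, if (x$focal_present) "" else " [absent]",
              paste(x$downstream, collapse = "-")))
  invisible(x)
}

# left-to-right arrangement of a locus window (k genes per side)
locus_arrangement <- function(l, k = Inf) {
  up <- utils::head(l$upstream, k)
  dn <- utils::head(l$downstream, k)
  c(rev(up), l$focal_gene, dn)
}

#' Compare two loci within a flanking window
#'
#' Computes the shared flanking markers, splits them into same-side versus
#' shuffled (present on the opposite side of the focal gene), and scores
#' order conservation. The adjacency score is the fraction of ordered
#' adjacent pairs of A's window (including the two pairs adjacent to the
#' focal gene) that recur as adjacent ordered pairs in B's window; the
#' Jaccard index is the symmetric overlap of the two marker sets.
#'
#' @param A,B `locus` objects.
#' @param k Window: flanks truncated to `k` genes per side (default 7, the
#'   scale of the largest neighborhoods usually tabulated).
#' @return A list of class `synteny_comparison`: `shared_markers`,
#'   `same_side`, `shuffled`, `adjacency_score`, `jaccard`.
#' @export
compare_loci <- function(A, B, k = 7) {
  if (k < 1) stop("window k must be >= 1")
  a_up <- utils::head(A$upstream, k); a_dn <- utils::head(A$downstream, k)
  b_up <- utils::head(B$upstream, k); b_dn <- utils::head(B$downstream, k)
  a_all <- c(a_up, a_dn); b_all <- c(b_up, b_dn)
  if (length(a_all) == 0 && length(b_all) == 0)
    stop("both loci have empty flanks; comparison undefined")
  shared <- intersect(a_all, b_all)
  same_side <- c(intersect(a_up, b_up), intersect(a_dn, b_dn))
  shuffled <- setdiff(shared, same_side)

  arrA <- locus_arrangement(A, k); arrB <- locus_arrangement(B, k)
  # map focal genes onto a common token so focal adjacencies can match
  arrA[arrA == A$focal_gene] <- "<FOCAL>"
  arrB[arrB == B$focal_gene] <- "<FOCAL>"
  pairsA <- if (length(arrA) > 1)
    paste(arrA[-length(arrA)], arrA[-1], sep = ">") else character(0)
  pairsB <- if (length(arrB) > 1)
    paste(arrB[-length(arrB)], arrB[-1], sep = ">") else character(0)
  adjacency <- if (length(pairsA) == 0) NA_real_ else
    sum(pairsA %in% pairsB) / length(pairsA)
  jac <- if (length(union(a_all, b_all)) == 0) NA_real_ else
    length(shared) / length(union(a_all, b_all))
  structure(list(shared_markers = shared, same_side = same_side,
                 shuffled = shuffled, adjacency_score = adjacency,
                 jaccard = jac),
            class = "synteny_comparison")
}

#' @export
print.synteny_comparison <- function(x, ...) {
  cat(sprintf("<synteny_comparison> %d shared (%d same side, %d shuffled); adjacency %.2f, jaccard %.2f\n",
              length(x$shared_markers), length(x$same_side),
              length(x$shuffled), x$adjacency_score, x$jaccard))
  invisible(x)
}

#' Ancestral-locus support across species
#'
#' A species supports a candidate ancestral locus when *all* marker symbols
#' co-occur in its locus window (conjunctive rule): a single conserved
#' marker pair (e.g. a P2RY6-class receptor next to the focal gene) read in
#' several lineages is what anchors an ancestral locus.
#'
#' @param loci List of `locus` objects.
#' @param markers Non-empty character vector of marker symbols.
#' @param k Window (genes per side).
#' @return A list with `supported` (named logical per species),
#'   `supporting_species`, `markers`.
#' @export
ancestral_support <- function(loci, markers, k = 7) {
  markers <- toupper(markers)
  if (length(markers) == 0) stop("marker set must be non-empty")
  supported <- vapply(loci, function(l) {
    all(markers %in% c(utils::head(l$upstream, k), utils::head(l$downstream, k)))
  }, TRUE)
  names(supported) <- vapply(loci, `[[`, "", "species")
  list(supported = supported,
       supporting_species = names(supported)[supported],
       markers = markers)
}

#' Conserved flanking signature per paralog set
#'
#' For each set of paralogous loci (e.g. the three ray-finned-fish copies of
#' a duplicated gene), derives the conserved signature: symbols present in at
#' least half of the set's loci, ordered by their median position across the
#' arrangements. Loci that retain at least half of the signature but lack
#' the focal gene are reported as focal-gene losses — the "marker genes
#' still there, gene itself gone" pattern.
#'
#' @param loci_by_set Named list: paralog-set name -> list of `locus`
#'   objects (>= 1 per set).
#' @param k Window (genes per side).
#' @return Named list per set: `signature` (ordered symbols),
#'   `focal_losses` (species), `n_loci`.
#' @export
classify_copy_loci <- function(loci_by_set, k = 7) {
  lapply(loci_by_set, function(set) {
    n <- length(set)
    arrs <- lapply(set, locus_arrangement, k = k)
    flank_syms <- lapply(set, function(l)
      c(utils::head(l$upstream, k), utils::head(l$downstream, k)))
    tab <- table(unlist(flank_syms))
    sig <- names(tab)[tab >= n / 2]
    med_rank <- vapply(sig, function(s) {
      stats::median(vapply(arrs, function(a) {
        i <- match(s, a)
        if (is.na(i)) NA_real_ else as.numeric(i)
      }, 0), na.rm = TRUE)
    }, 0)
    sig <- sig[order(med_rank)]
    losses <- vapply(set, function(l) {
      syms <- c(utils::head(l$upstream, k), utils::head(l$downstream, k))
      !l$focal_present && length(sig) > 0 &&
        sum(sig %in% syms) >= length(sig) / 2
    }, TRUE)
    list(signature = sig,
         focal_losses = vapply(set, `[[`, "", "species")[losses],
         n_loci = n)
  })
}

#' Read loci from a TSV file
#'
#' Expected columns: `species`, `focal_gene`, `side` (`U`/`D`), `rank`
#' (1 = nearest), `symbol`, optional `strand`. A row with side `F` and the
#' focal symbol may mark focal-gene absence with `symbol` = `X`.
#'
#' @param path TSV path.
#' @return Named list of `locus` objects (one per species/focal pair).
#' @export
read_locus_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "focal_gene", "side", "rank", "symbol")
  if (!all(need %in% names(df)))
    stop("locus TSV must have columns: ", paste(need, collapse = ", "))
  out <- list()
  for (key in unique(paste(df$species, df$focal_gene, sep = "\r"))) {
    sub <- df[paste(df$species, df$focal_gene, sep = "\r") == key, ]
    up <- sub[sub$side == "U", ]; up <- up[order(up$rank), ]
    dn <- sub[sub$side == "D", ]; dn <- dn[order(dn$rank), ]
    absent <- any(sub$side == "F" & toupper(sub$symbol) == "X")
    l <- locus(species = sub$species[1], focal_gene = sub$focal_gene[1],
               upstream = up$symbol, downstream = dn$symbol,
               focal_present = !absent)
    # one locus per species keys by species; paralog loci key by focal@species
    nm <- if (length(unique(df$focal_gene[df$species == sub$species[1]])) == 1)
      sub$species[1] else paste0(sub$focal_gene[1], "@", sub$species[1])
    out[[nm]] <- l
  }
  out
}

#' Write loci to a TSV file
#' @param loci List of `locus` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_locus_tsv <- function(loci, path) {
  rows <- lapply(loci, function(l) {
    df <- data.frame(species = l$species, focal_gene = l$focal_gene,
                     side = c(rep("U", length(l$upstream)),
                              rep("D", length(l$downstream))),
                     rank = c(seq_along(l$upstream), seq_along(l$downstream)),
                     symbol = c(l$upstream, l$downstream))
    if (!l$focal_present)
      df <- rbind(df, data.frame(species = l$species, focal_gene = l$focal_gene,
                                 side = "F", rank = 0, symbol = "X"))
    df
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
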