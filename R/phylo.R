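#' p-distance between two aligned sequences
#'
#' Fraction of mismatching positions over columns where both sequences carry a
#' residue; any column with a gap in either sequence is excluded.
#'
#' @param a,b Equal-length gapped sequence strings.
#' @return Numeric distance in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) stop("sequences differ in aligned length")
  keep <- va != "-" & vb != "-"
  n <- sum(keep)
  if (n == 0) stop("no comparable (gap-free) columns between the two sequences")
  sum(va[keep] != vb[keep]) / n
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln A [multiple_alignment()] or named character vector of aligned
#'   rows.
#' @param include_reference Keep the reference row in the matrix? Defaults to
#'   `TRUE`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln, include_reference = TRUE) {
  rows <- if (inherits(aln, "multiple_alignment")) aln$rows else aln
  if (inherits(aln, "multiple_alignment") && !include_reference)
    rows <- rows[setdiff(names(rows), aln$reference_name)]
  n <- length(rows)
  D <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        D[i, j] <- D[j, i] <- p_distance(rows[[i]], rows[[j]])
      }
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration. Ties in the Q criterion are broken
#' deterministically by the lexicographically smallest pair of cluster
#' representatives (each cluster is represented by its smallest leaf label),
#' so the same matrix always yields the same tree. Negative branch lengths,
#' which NJ can produce on non-additive input, are clamped to zero with a
#' warning.
#'
#' @param D Symmetric distance matrix with row/column names and zero
#'   diagonal; at least 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  if (is.null(rownames(D))) stop("D must have taxon labels")
  if (max(abs(D - t(D))) > 1e-9) stop("D must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("neighbor-joining needs at least 3 taxa")

  labels <- rownames(D)
  # each active cluster: newick fragment + representative (smallest leaf label)
  frag <- labels
  rep_ <- labels
  neg <- FALSE
  bl <- function(x) { if (x < -1e-12) neg <<- TRUE; format(max(x, 0), digits = 15) }

  while (length(frag) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        if (Q[i, j] <= qmin + 1e-12) {
          key <- sort(c(rep_[i], rep_[j]))
          if (is.null(best) || key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])) {
            best <- list(i = i, j = j, key = key)
          }
        }
      }
    }
    i <- best$i; j <- best$j
    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], bl(li), frag[j], bl(lj))
    newrep <- min(rep_[i], rep_[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_ <- c(rep_[keep], newrep)
    D <- D2
  }
  # final 3-cluster star, closed form
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 frag[1], bl(la), frag[2], bl(lb), frag[3], bl(lc))
  if (neg) warning("negative NJ branch length(s) clamped to 0")
  ape::read.tree(text = nwk)
}

#' Dollo-parsimony placement of a binary character on a rooted tree
#'
#' Under Dollo parsimony a character (here: an intron at a given reference
#' position) is gained exactly once and may be lost any number of times. The
#' gain is placed on the branch above the most recent common ancestor of all
#' leaves scored present; losses are the minimal set of branches whose
#' subtrees contain at least one absent leaf and no present leaf. Leaves
#' scored unknown (NA; e.g. partial gene models) never force a loss.
#'
#' @param tree A rooted `phylo` tree.
#' @param presence Named vector over the tree's tip labels: 1 (present),
#'   0 (absent), or NA (unknown).
#' @return A list of class `dollo_events`: `gain_node` (node number of the
#'   branch's child; NA when the character is absent everywhere),
#'   `gain_clade` (tip labels below the gain), `loss_nodes`, `loss_clades`,
#'   `n_losses`.
#' @export
dollo_events <- function(tree, presence) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted for Dollo inference")
  tips <- tree$tip.label
  if (!all(tips %in% names(presence)))
    stop("presence vector must cover every tip label")
  p <- presence[tips]
  if (!all(p %in% c(0, 1) | is.na(p))) stop("presence values must be 0, 1 or NA")

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  present_tips <- which(!is.na(p) & p == 1)
  if (length(present_tips) == 0) {
    return(structure(list(gain_node = NA_integer_, gain_clade = character(0),
                          loss_nodes = integer(0), loss_clades = list(),
                          n_losses = 0L),
                     class = "dollo_events"))
  }
  gain <- if (length(present_tips) == 1) present_tips else
    ape::getMRCA(tree, present_tips)

  # per-node counts of present / absent known leaves, by postorder accumulation
  npres <- nabs <- integer(ntip + nnode)
  npres[seq_len(ntip)] <- as.integer(!is.na(p) & p == 1)
  nabs[seq_len(ntip)] <- as.integer(!is.na(p) & p == 0)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    npres[par] <- npres[par] + npres[ch]
    nabs[par] <- nabs[par] + nabs[ch]
  }

  # losses: maximal nodes inside the gain clade with no present and >=1 absent
  children <- split(edge[, 2], edge[, 1])
  losses <- integer(0)
  visit <- function(v) {
    for (ch in children[[as.character(v)]]) {
      if (npres[ch] == 0) {
        if (nabs[ch] > 0) losses <<- c(losses, ch)
        # unknown-only subtree: unconstrained, no loss required
      } else if (ch > ntip) {
        visit(ch)
      }
    }
  }
  if (gain > ntip) visit(gain)
  clade_tips <- function(v) {
    if (v <= ntip) return(tips[v])
    tips[ape::prop.part(tree)[[v - ntip]]]
  }
  structure(list(gain_node = as.integer(gain),
                 gain_clade = clade_tips(gain),
                 loss_nodes = as.integer(losses),
                 loss_clades = lapply(losses, clade_tips),
                 n_losses = length(losses)),
            class = "dollo_events")
}

#' @export
print.dollo_events <- function(x, ...) {
  if (is.na(x$gain_node)) {
    cat("<dollo_events> character absent everywhere; no events\n")
    return(invisible(x))
  }
  cat(sprintf("<dollo_events> 1 gain above node %d (%d leaves), %d loss(es)\n",
              x$gain_node, length(x$gain_clade), x$n_losses))
  invisible(x)
}

#' Duplication nodes of a gene tree by the species-overlap rule
#'
#' An internal node of a gene tree is a duplication node when the species
#' sets of its child subtrees intersect: the same species appearing on both
#' sides means the gene lineages had already split within that genome.
#'
#' @param gene_tree A rooted `phylo` tree whose tips are genes.
#' @param species Named character vector mapping tip label to species. When
#'   omitted, tip labels of the form `"gene@species"` are parsed.
#' @return Integer vector of duplication node numbers (ape numbering), with
#'   a `species_sets` attribute listing each node's child species sets.
#' @export
duplication_nodes <- function(gene_tree, species = NULL) {
  tips <- gene_tree$tip.label
  if (is.null(species)) {
    if (!all(grepl("@", tips)))
      stop("tip labels must be 'gene@species' or a species map supplied")
    species <- stats::setNames(sub("^.*@", "", tips), tips)
  }
  if (!all(tips %in% names(species))) stop("species map must cover every tip")
  ntip <- ape::Ntip(gene_tree)
  edge <- ape::reorder.phylo(gene_tree, "postorder")$edge
  spset <- vector("list", ntip + gene_tree$Nnode)
  for (i in seq_len(ntip)) spset[[i]] <- species[[tips[i]]]
  children <- split(edge[, 2], edge[, 1])
  dup <- integer(0)
  sets <- list()
  # accumulate species sets bottom-up
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]; ch <- edge[k, 2]
    spset[[par]] <- union(spset[[par]], spset[[ch]])
  }
  for (v in (ntip + 1):(ntip + gene_tree$Nnode)) {
    kids <- children[[as.character(v)]]
    kidsets <- lapply(kids, function(ch) spset[[ch]])
    overlap <- FALSE
    if (length(kidsets) > 1) {
      for (i in seq_len(length(kidsets) - 1)) {
        for (j in (i + 1):length(kidsets)) {
          if (length(intersect(kidsets[[i]], kidsets[[j]])) > 0) overlap <- TRUE
        }
      }
    }
    if (overlap) { dup <- c(dup, v); sets[[as.character(v)]] <- kidsets }
  }
  structure(dup, species_sets = sets)
}

#' Date an event placed on a branch of an ultrametric tree
#'
#' An event assigned to a branch can have happened anywhere along it, so its
#' age interval is `[age(child), age(parent)]` in MY.
#'
#' @param tree Ultrametric `phylo` with branch lengths in MY.
#' @param branch_node Node number of the branch's child end (as reported by
#'   [dollo_events()] or [duplication_nodes()]).
#' @return Numeric vector `c(younger, older)`.
#' @export
date_event <- function(tree, branch_node) {
  ages <- node_ages(tree)
  edge <- tree$edge
  k <- which(edge[, 2] == branch_node)
  if (length(k) != 1) {
    if (branch_node == ape::Ntip(tree) + 1)  # root: degenerate interval
      return(c(ages[branch_node], ages[branch_node]))
    stop("node ", branch_node, " has no parent branch in the tree")
  }
  c(younger = unname(ages[branch_node]), older = unname(ages[edge[k, 1]]))
}

#' Render an age interval the way divergence dates are usually printed
#'
#' @param interval Numeric `c(younger, older)` from [date_event()].
#' @return A string such as `"416-360 MYA"` (older first).
#' @export
format_age_interval <- function(interval) {
  sprintf("%g–%g MYA", max(interval), min(interval))
}
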