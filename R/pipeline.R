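#' Run the full comparative-architecture pipeline
#'
#' Orchestrates the analysis end to end: intron labelling against the
#' reference row, architecture comparison against the ancestral intron set,
#' Dollo placement (and, on a time-calibrated tree, dating) of every novel
#' intron label, duplication detection on a neighbor-joining gene tree built
#' from p-distances, synteny classification of the paralog loci, and the
#' sequence-feature report. Accepts either a [simulate_gene_family()] result
#' or a list of the same components read from files.
#'
#' @param inputs A `gene_family_simulation`, or a list with elements
#'   `models` (named list of [gene_model()], names matching alignment rows),
#'   `alignment` (a [multiple_alignment()]), `species_tree` (`phylo`),
#'   `loci` (named list of [locus()]; optional), and optionally `cds`
#'   (named vector for translation checks).
#' @param reference_labels Ancestral intron label set.
#' @param out_dir Optional directory for TSV/JSON stage outputs plus a run
#'   manifest.
#' @param p1_column Optional P1 alignment column for RCL annotation.
#' @param canonical Optional canonical-residue table for the checklist.
#' @return A list of class `introscape_report` with `labels`, `profiles`,
#'   `gain_loss`, `events` (per novel label: gain branch, losses, age
#'   interval when datable), `gene_tree`, `duplications`, `synteny`,
#'   `features`.
#' @export
run_pipeline <- function(inputs,
                         reference_labels = c("192a", "225a", "300c"),
                         out_dir = NULL, p1_column = NULL, canonical = NULL) {
  sim <- if (inherits(inputs, "gene_family_simulation")) inputs else NULL
  models <- inputs$models
  aln <- inputs$alignment
  tree <- inputs$species_tree
  loci <- inputs$loci
  cds <- inputs$cds

  if (length(models) == 0) {
    rep <- structure(list(labels = data.frame(), profiles = list(),
                          gain_loss = NULL, events = list(),
                          gene_tree = NULL, duplications = integer(0),
                          synteny = list(), features = NULL),
                     class = "introscape_report")
    if (!is.null(out_dir)) write_report(rep, out_dir, inputs)
    return(rep)
  }

  # stage 1: intron labels + profiles
  labels <- list(); profiles <- list()
  for (nm in names(models)) {
    lab <- label_introns(models[[nm]], aln,
                         cds = if (!is.null(cds)) cds[[nm]] else NULL,
                         gene_name = nm)
    labels[[nm]] <- lab
    profiles[[nm]] <- architecture_profile(models[[nm]], lab)
  }
  label_tab <- do.call(rbind, labels)

  # stage 2: gain/loss matrix
  glm <- compare_architectures(profiles, reference_labels)

  # stage 3: Dollo events per novel label, on the species tree
  species_of <- vapply(names(models), function(nm) sub("^.*@", "", nm), "")
  datable <- ape::is.ultrametric(tree, tol = 1e-6)
  events <- list()
  for (lb in glm$novel_labels) {
    col <- glm$matrix[, lb]
    pres <- stats::setNames(rep(NA_real_, ape::Ntip(tree)), tree$tip.label)
    for (sp in tree$tip.label) {
      vals <- col[species_of[rownames(glm$matrix)] == sp]
      pres[sp] <- if (any(vals == "P")) 1 else if (any(vals == "A")) 0 else NA
    }
    de <- dollo_events(tree, pres)
    interval <- if (!is.na(de$gain_node) && datable)
      date_event(tree, de$gain_node) else NULL
    events[[lb]] <- list(label = lb, dollo = de, age_interval = interval)
  }

  # stage 4: gene tree (NJ on p-distances) + duplication nodes
  gene_rows <- aln$rows[names(models)]
  gene_tree <- NULL; dups <- integer(0)
  if (length(gene_rows) >= 3) {
    D <- p_distance_matrix(gene_rows)
    gene_tree <- nj_tree(D)
    spmap <- stats::setNames(species_of[names(models)], names(models))
    rooted <- root_gene_tree(gene_tree, spmap)
    dups <- duplication_nodes(rooted, species = spmap)
    gene_tree <- rooted
  }

  # stage 5: synteny (loci grouped by paralog copy)
  synteny <- list()
  if (length(loci)) {
    copy_of <- vapply(names(loci), function(nm) sub("@.*$", "", nm), "")
    synteny <- classify_copy_loci(split(unname(loci), copy_of))
  }

  # stage 6: features
  features <- feature_report(aln, canonical = canonical,
                             p1_column = p1_column)

  rep <- structure(list(labels = label_tab, profiles = profiles,
                        gain_loss = glm, events = events,
                        gene_tree = gene_tree, duplications = dups,
                        synteny = synteny, features = features),
                   class = "introscape_report")
  if (!is.null(out_dir)) write_report(rep, out_dir, inputs)
  rep
}

# minimal-duplication rooting: try every branch as the root position and
# keep the rooting implying the fewest species-overlap duplications
# (deterministic: first minimal branch in edge order)
root_gene_tree <- function(tree, species) {
  if (ape::is.rooted(tree)) return(tree)
  best <- NULL; best_n <- Inf
  for (k in seq_len(nrow(tree$edge))) {
    node <- tree$edge[k, 2]
    cand <- tryCatch({
      if (node <= ape::Ntip(tree))
        ape::root(tree, outgroup = tree$tip.label[node], resolve.root = TRUE)
      else
        ape::root(tree, node = node, resolve.root = TRUE)
    }, error = function(e) NULL)
    if (is.null(cand)) next
    n <- length(duplication_nodes(cand, species = species))
    if (n < best_n) { best <- cand; best_n <- n }
  }
  best
}

#' @export
print.introscape_report <- function(x, ...) {
  cat("<introscape_report>\n")
  cat(" genes:", length(x$profiles), "\n")
  if (!is.null(x$gain_loss))
    cat(" novel labels:", paste(x$gain_loss$novel_labels, collapse = ", "), "\n")
  for (ev in x$events) {
    if (is.na(ev$dollo$gain_node)) next
    cat(sprintf(" event %s: gain above node %d, %d loss(es)%s\n",
                ev$label, ev$dollo$gain_node, ev$dollo$n_losses,
                if (!is.null(ev$age_interval))
                  paste0(", ", format_age_interval(ev$age_interval)) else ""))
  }
  cat(" duplication nodes:", length(x$duplications), "\n")
  invisible(x)
}

write_report <- function(rep, out_dir, inputs) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(rep$labels))
    write_intron_tsv(rep$labels, file.path(out_dir, "intron_labels.tsv"))
  if (!is.null(rep$gain_loss))
    write_gain_loss_tsv(rep$gain_loss, file.path(out_dir, "gain_loss.tsv"))
  ev <- lapply(rep$events, function(e) {
    list(label = e$label,
         gain_node = e$dollo$gain_node,
         gain_clade = e$dollo$gain_clade,
         loss_clades = e$dollo$loss_clades,
         n_losses = e$dollo$n_losses,
         age_interval = e$age_interval)
  })
  jsonlite::write_json(unname(ev), file.path(out_dir, "events.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(rep$gene_tree))
    ape::write.tree(rep$gene_tree, file.path(out_dir, "gene_tree.nwk"))
  if (length(rep$synteny))
    jsonlite::write_json(rep$synteny, file.path(out_dir, "synteny.json"),
                         auto_unbox = TRUE)
  utils::write.table(rep$features$conservation$columns,
                     file.path(out_dir, "conservation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  files <- setdiff(list.files(out_dir), "manifest.json")
  jsonlite::write_json(
    list(tool = paste0("introscape ",
                       as.character(utils::packageVersion("introscape"))),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         outputs = as.list(stats::setNames(
           unname(tools::md5sum(file.path(out_dir, files))), files))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  invisible(out_dir)
}
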