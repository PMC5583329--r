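small_tree <- function() {
  ape::read.tree(text = "((A:50,B:50)AB:50,(C:60,D:60)CD:40)R;")
}

test_that("the same seed reproduces fixtures byte for byte", {
  cfg <- simulation_config(seed = 123)
  s1 <- simulate_gene_family(cfg)
  s2 <- simulate_gene_family(cfg)
  expect_identical(s1$proteins, s2$proteins)
  expect_identical(s1$cds, s2$cds)
  expect_identical(s1$truth$events, s2$truth$events)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in c("proteins.faa", "cds.fna", "alignment.faa", "loci.tsv",
              "truth_log.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("the null model (zero rate, no events) leaves every leaf identical to the root", {
  cfg <- simulation_config(species_tree = small_tree(),
                           substitution_rate = 0, events = list(), seed = 5)
  sim <- simulate_gene_family(cfg)
  expect_equal(length(unique(unname(sim$proteins))), 1)
  # intron labels identical across leaves
  labs <- lapply(names(sim$models), function(nm)
    label_introns(sim$models[[nm]], sim$alignment, gene_name = nm)$label)
  expect_equal(length(unique(labs)), 1)
  expect_equal(labs[[1]], c("192a", "225a", "300c"))
})

test_that("scripted gains are carried by exactly the descendant leaves", {
  sim <- simulate_gene_family(simulation_config(seed = 2))
  gained_species <- c("cod", "fugu", "stickleback", "tilapia", "medaka",
                      "platyfish", "molly")
  for (nm in names(sim$models)) {
    if (!grepl("^HSP47_1@", nm)) next
    sp <- sub("^.*@", "", nm)
    lab <- label_introns(sim$models[[nm]], sim$alignment, gene_name = nm)
    has_gain <- all(c("36b", "102b") %in% lab$label)
    expect_equal(has_gain, sp %in% gained_species, info = nm)
    # conserved ancestral introns everywhere
    expect_true(all(c("192a", "225a", "300c") %in% lab$label), info = nm)
  }
  # other copies never carry the gains
  for (nm in grep("^HSP47_[23]@", names(sim$models), value = TRUE)) {
    lab <- label_introns(sim$models[[nm]], sim$alignment, gene_name = nm)
    expect_false(any(c("36b", "102b") %in% lab$label), info = nm)
  }
})

test_that("scripted duplications produce three paralog sets recovered on the true gene tree", {
  sim <- simulate_gene_family(simulation_config(seed = 3))
  copies <- unique(sub("@.*$", "", names(sim$models)))
  expect_setequal(copies, c("HSP47_1", "HSP47_2", "HSP47_3"))
  # tetrapods keep a single copy; fishes have three
  expect_equal(sum(grepl("@tetrapods$", names(sim$models))), 1)
  expect_equal(sum(grepl("@medaka$", names(sim$models))), 3)
  tg <- true_gene_tree(sim)
  d <- duplication_nodes(tg)
  expect_equal(length(d), 2)   # every scripted duplication, nothing else
})

test_that("closed-form identity calibration matches Monte-Carlo simulation", {
  expect_equal(calibrate_identity(0, 100), 100)
  expect_lt(calibrate_identity(1, 1e5) - 5, 1e-6)   # saturation floor
  depth <- 100
  rate <- rate_for_identity(65, depth)
  expect_equal(calibrate_identity(rate, depth), 65, tolerance = 1e-10)
  two <- ape::read.tree(text = "(X:100,Y:100)R;")
  ids <- vapply(1:50, function(i) {
    cfg <- simulation_config(species_tree = two, substitution_rate = rate,
                             events = list(), seed = 1000 + i)
    sim <- simulate_gene_family(cfg)
    percent_identity(sim$alignment$rows[["HSP47_1@X"]],
                     sim$alignment$rows[["HSP47_1@Y"]], digits = 2)
  }, 0)
  expect_lt(abs(mean(ids) - 65), 3)
})

test_that("locus shuffles and losses are recoverable from the emitted loci", {
  cfg <- simulation_config(
    species_tree = small_tree(), events = list(
      list(branch = "CD", type = "locus_shuffle", gene = "HSP47_1",
           symbol = "RPS3"),
      list(branch = "D", type = "locus_loss", gene = "HSP47_1",
           symbol = "MAP6"),
      list(branch = "C", type = "locus_loss", gene = "HSP47_1",
           symbol = "HSP47")),
    seed = 8)
  sim <- simulate_gene_family(cfg)
  ancestral <- locus("root", "HSP47_1",
                     upstream = cfg$root_locus$upstream,
                     downstream = cfg$root_locus$downstream)
  cmpC <- compare_loci(ancestral, sim$loci[["HSP47_1@C"]])
  expect_true("RPS3" %in% cmpC$shuffled)
  cmpA <- compare_loci(ancestral, sim$loci[["HSP47_1@A"]])
  expect_equal(cmpA$shuffled, character(0))
  expect_false("MAP6" %in%
                 c(sim$loci[["HSP47_1@D"]]$upstream,
                   sim$loci[["HSP47_1@D"]]$downstream))
  expect_false(sim$loci[["HSP47_1@C"]]$focal_present)
  expect_true(sim$loci[["HSP47_1@A"]]$focal_present)
})

test_that("codon indels shift downstream intron offsets but not labels", {
  cfg <- simulation_config(
    species_tree = small_tree(), substitution_rate = 1e-4,
    events = list(list(branch = "AB", type = "codon_indel",
                       gene = "HSP47_1", exon = 1, codons = -2)),
    seed = 4)
  sim <- simulate_gene_family(cfg)
  mA <- sim$models[["HSP47_1@A"]]
  expect_equal(introns_of(mA)$coding_offset, c(568L, 667L, 894L))
  labA <- label_introns(mA, sim$alignment, gene_name = "HSP47_1@A")
  # projection through the true alignment restores reference numbering
  expect_equal(labA$label, c("192a", "225a", "300c"))
  mC <- sim$models[["HSP47_1@C"]]
  expect_equal(introns_of(mC)$coding_offset, c(574L, 673L, 900L))
})

test_that("simulated CDS translate to the emitted proteins and genomic fixtures parse", {
  sim <- simulate_gene_family(simulation_config(
    species_tree = small_tree(), events = list(), seed = 6))
  nm <- "HSP47_1@A"
  tr <- as.character(Biostrings::translate(Biostrings::DNAString(sim$cds[[nm]])))
  expect_equal(sub("\\*$", "", tr), unname(sim$proteins[nm]))
  # genomic sequence: exon substrings reproduce the CDS
  g <- simulated_genomic_seq(sim, nm)
  m <- sim$models[[nm]]
  cds_back <- paste(apply(m$cds_exons, 1, function(e)
    substr(g, e[1] + 1, e[2])), collapse = "")
  expect_equal(cds_back, unname(sim$cds[nm]))
  # and the written GFF3 round-trips the model
  d <- withr::local_tempdir()
  write_simulation(sim, d)
  back <- read_gff3(file.path(d, "A.gff3"))
  expect_equal(unname(back[[1]]$cds_exons), unname(m$cds_exons))
})

test_that("events on unknown branches or occupied offsets are config errors", {
  expect_error(simulation_config(events = list(
    list(branch = "nosuch", type = "duplication", gene = "HSP47_1"))),
    "unknown branch")
  cfg <- simulation_config(species_tree = small_tree(), events = list(
    list(branch = "AB", type = "intron_gain", gene = "HSP47_1",
         offset = 574, length = 100)), seed = 1)
  expect_error(simulate_gene_family(cfg), "occupied")
})
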