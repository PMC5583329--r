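profile_of <- function(offsets, gene_id = "G1", partial = FALSE,
                       aln = make_identity_alignment(gene_id = gene_id)) {
  m <- make_collinear_gene(offsets = offsets, gene_id = gene_id)
  m$partial <- partial
  lab <- label_introns(m, aln, gene_name = gene_id)
  architecture_profile(m, lab)
}

test_that("profiles report the exon/intron pattern string", {
  expect_equal(profile_of(c(574, 673, 900))$pattern, "4e/3i")
  expect_equal(profile_of(c(107, 305, 574, 673, 900))$pattern, "6e/5i")
  aln1 <- make_identity_alignment(n_codons = 11, gene_id = "G1")
  m1 <- gene_model("G1", cds_exons = cbind(0, 33))
  p1 <- architecture_profile(m1, label_introns(m1, aln1, gene_name = "G1"))
  expect_equal(p1$pattern, "1e/0i")
  expect_equal(pattern_exons(p1$pattern), 1L)
})

test_that("gain/loss comparison separates novel from conserved labels", {
  fish <- profile_of(c(107, 305, 574, 673, 900), gene_id = "fish1")
  tetra <- profile_of(c(574, 673, 900), gene_id = "tetra1")
  glm <- compare_architectures(list(fish, tetra))
  expect_setequal(glm$gains[["fish1"]], c("36b", "102b"))
  expect_equal(glm$losses[["fish1"]], character(0))
  expect_equal(glm$gains[["tetra1"]], character(0))
  expect_equal(glm$losses[["tetra1"]], character(0))
  expect_setequal(glm$novel_labels, c("36b", "102b"))
  expect_equal(glm$matrix["tetra1", "36b"], "A")
})

test_that("partial genes yield unknown, never loss", {
  # a gene whose 192a intron could not be identified, flagged partial
  part <- profile_of(c(673, 900), gene_id = "tni", partial = TRUE)
  glm <- compare_architectures(list(part))
  expect_equal(glm$matrix["tni", "192a"], "U")
  expect_equal(glm$losses[["tni"]], character(0))
  # the same architecture NOT flagged partial is a loss call
  full <- profile_of(c(673, 900), gene_id = "xyz")
  glm2 <- compare_architectures(list(full))
  expect_equal(glm2$matrix["xyz", "192a"], "A")
  expect_equal(glm2$losses[["xyz"]], "192a")
})

test_that("comparison is idempotent, permutation-invariant, and rejects duplicates", {
  a <- profile_of(c(574, 673, 900), gene_id = "a")
  b <- profile_of(c(107, 574, 673, 900), gene_id = "b")
  g1 <- compare_architectures(list(a, b))
  g2 <- compare_architectures(list(b, a))
  expect_equal(g1$matrix[sort(rownames(g1$matrix)), ],
               g2$matrix[sort(rownames(g2$matrix)), ])
  expect_equal(g1$gains, compare_architectures(list(a, b))$gains)
  expect_error(compare_architectures(list(a, a)), "duplicate")
})

test_that("near-miss labels are kept distinct with a proximity warning", {
  a <- profile_of(c(574), gene_id = "a")           # 192a
  b <- profile_of(c(577), gene_id = "b")           # 193a
  glm <- compare_architectures(list(a, b), reference_labels = character(0))
  expect_true(all(c("192a", "193a") %in% colnames(glm$matrix)))
  expect_match(glm$proximity_warnings, "192a and 193a")
})

test_that("two intron insertions turn a 4e/3i model into 6e/5i, CDS unchanged", {
  m <- make_collinear_gene(offsets = c(574, 673, 900))
  m2 <- insert_intron(m, 107, 120)
  m3 <- insert_intron(m2, 305, 130)
  expect_equal(nrow(m3$cds_exons), 6)
  expect_equal(cds_length(m3), cds_length(m))
  expect_equal(introns_of(m3)$coding_offset, c(107L, 305L, 574L, 673L, 900L))
  aln <- make_identity_alignment()
  expect_equal(label_introns(m3, aln, gene_name = "G1")$label,
               c("36b", "102b", "192a", "225a", "300c"))
})

test_that("intron insertion preserves the encoded CDS sequence exactly", {
  set.seed(5)
  m <- gene_model("g", cds_exons = cbind(c(0, 40, 90), c(30, 80, 150)))
  genome <- paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                  collapse = "")
  extract_cds <- function(model, genome) {
    paste(apply(model$cds_exons, 1, function(e)
      substr(genome, e[1] + 1, e[2])), collapse = "")
  }
  before <- extract_cds(m, genome)
  # splice an intron into the genomic string at coding offset 50
  # (exon 2 starts at genomic 40, coding offset 30 -> split at genomic 60)
  intron <- paste(rep("T", 25), collapse = "")
  genome2 <- paste0(substr(genome, 1, 60), intron, substr(genome, 61, 200))
  m2 <- insert_intron(m, 50, 25)
  expect_equal(extract_cds(m2, genome2), before)
})

test_that("insertion at a junction or boundary is rejected; edits invert", {
  m <- make_collinear_gene(offsets = c(574, 673, 900))
  expect_error(insert_intron(m, 0, 100), "strictly inside")
  expect_error(insert_intron(m, 574, 100), "strictly inside")
  m2 <- insert_intron(m, 107, 120)
  # conceptual removal: the profile with the new label dropped equals the old
  expect_equal(setdiff(introns_of(m2)$coding_offset,
                       introns_of(m)$coding_offset), 107)
  expect_equal(exon_lengths(m2)[1] + exon_lengths(m2)[2], exon_lengths(m)[1])
})

test_that("minus-strand insertion behaves identically in coding coordinates", {
  plus <- gene_model("p", strand = "+",
                     cds_exons = cbind(c(0, 100), c(60, 160)))
  minus <- gene_model("m", strand = "-",
                      cds_exons = cbind(c(100, 0), c(160, 60)))
  p2 <- insert_intron(plus, 30, 50)
  m2 <- insert_intron(minus, 30, 50)
  expect_equal(exon_lengths(p2), exon_lengths(m2))
  expect_equal(introns_of(p2)$length, introns_of(m2)$length)
})

test_that("codon indels resize one exon by whole codons", {
  # the conserved serpin exon sizes eI-eIV
  m <- make_sized_gene(c(574, 99, 233, 303))
  expect_equal(exon_lengths(m)[4], 303L)
  plus1 <- apply_codon_indel(m, 4, +1)
  expect_equal(exon_lengths(plus1)[4], 306L)
  expect_equal(cds_length(plus1) %% 3, 0)

  minus2 <- apply_codon_indel(m, 2, -2)
  expect_equal(exon_lengths(minus2)[2], 93L)
  expect_equal(introns_of(minus2)$length, introns_of(m)$length)

  expect_identical(apply_codon_indel(m, 2, 0), m)
  expect_error(apply_codon_indel(m, 2, -33), "exceeds")
})

test_that("size tables report per-position values and min-max ranges", {
  a <- profile_of(c(574, 673, 900), gene_id = "a")
  b <- profile_of(c(574, 673, 900), gene_id = "b")
  st <- size_table(list(a, b))
  expect_equal(unname(unlist(st$exons[, "e[192a:225a]"])), c(99L, 99L))
  rng <- attr(st, "range")
  eII <- rng$exons[rng$exons$position == "e[192a:225a]", ]
  expect_equal(c(eII$min, eII$max), c(99, 99))

  # intron size ranges across genes
  c1 <- profile_of(c(574, 673, 900), gene_id = "c1")
  st2 <- size_table(list(a, c1))
  expect_equal(attr(st2, "range")$introns$min,
               pmin(a$intron_sizes, c1$intron_sizes))

  empty <- size_table(list())
  expect_equal(nrow(empty$introns), 0)
})
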