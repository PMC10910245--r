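test_that("raw round-trip preserves dosages, ids and metadata", {
  g <- random_genotypes(20, 50, seed = 42, missing_rate = 0.05)
  path <- withr::local_tempfile(fileext = ".raw")
  write_raw(g, path)
  g2 <- read_raw(path, map = g$snps)
  expect_identical(unname(g2$values), unname(g$values))
  expect_identical(g2$sample_ids, g$sample_ids)
  expect_identical(g2$snps$id, g$snps$id)
  expect_identical(g2$snps$pos_bp, g$snps$pos_bp)
  expect_identical(g2$snps$alt_allele, g$snps$alt_allele)
})

test_that("raw reader transcribes a small fixture verbatim", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_G rs2_T rs3_A",
    "f1 s1 0 0 1 -9 0 1 2",
    "f2 s2 0 0 2 -9 2 NA 1"
  ), path)
  g <- read_raw(path)
  expect_equal(dim(g), c(2L, 3L))
  expect_equal(unname(g$values[1, ]), c(0, 1, 2))
  expect_equal(unname(g$values[2, ]), c(2, NA, 1))
  expect_equal(g$snps$alt_allele, c("G", "T", "A"))
  expect_error(read_raw(textConnection("")), "")
})

test_that("ped/map reader codes dosages against the minor allele", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c(
    "1 rs1 0 1000",
    "1 rs2 0 2000"
  ), map)
  # rs1: alleles A (5 copies) / G (1 copy) -> alt = G
  # rs2: all C except one missing pair
  writeLines(c(
    "f1 s1 0 0 1 2 A A C C",
    "f2 s2 0 0 1 1 A G C C",
    "f3 s3 0 0 2 2 A A 0 0"
  ), ped)
  g <- read_ped_map(ped, map)
  expect_equal(unname(g$values[, 1]), c(0, 1, 0))
  expect_equal(g$snps$alt_allele[1], "G")
  expect_true(is.na(g$values[3, 2]))
})

test_that("haploid and non-ACGT SNP records are excluded and counted", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(sprintf("1 rs%d 0 %d000", 1:5, 1:5), map)
  # rs3 haploid in s2 (one allele missing), others clean
  writeLines(c(
    "f1 s1 0 0 1 2 A A C C G G T T A G",
    "f2 s2 0 0 1 1 A G C C G 0 T T A A"
  ), ped)
  expect_message(g <- read_ped_map(ped, map), "excluded 1")
  expect_equal(ncol(g$values), 4L)
  expect_false("rs3" %in% g$snps$id)
  expect_equal(attr(g, "n_excluded"), 1L)

  # non-ACGT allele record is likewise rejected
  writeLines(c(
    "f1 s1 0 0 1 2 A A I D",
    "f2 s2 0 0 1 1 A G I I"
  ), ped)
  expect_message(g2 <- read_ped_map(ped, map = {
    writeLines(sprintf("1 rs%d 0 %d000", 1:2, 1:2), map); map
  }), "excluded 1")
  expect_equal(g2$snps$id, "rs1")
})

test_that("malformed ped line is reported with its line number", {
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines("1 rs1 0 1000", map)
  writeLines(c(
    "f1 s1 0 0 1 2 A A",
    "f2 s2 0 0 1 1 A"
  ), ped)
  expect_error(read_ped_map(ped, map), "line 2")
})

test_that("phenotype reader enforces binary status and loads covariates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "sample_id\tstatus\tage",
    "s1\t1\t70", "s2\t0\t65", "s3\t1\t80", "s4\t0\t72"
  ), path)
  pheno <- read_phenotypes(path)
  expect_equal(nrow(pheno), 4L)
  expect_equal(sum(pheno$status), 2L)
  expect_type(pheno$age, "double")

  writeLines(c("sample_id,status", "s1,1", "s2,2"), path)
  expect_error(read_phenotypes(path), "row 2")
})

test_that("phenotype round-trip through TSV is lossless", {
  pheno <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    status = c(1L, 0L, 1L, 0L, 0L, 1L),
    age = c(70, 65, 80, 72, 68, 75)
  )
  path <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(pheno, path)
  expect_equal(read_phenotypes(path), pheno)
})

test_that("alignment matches a brute-force id join under permutation", {
  set.seed(7)
  for (rep in 1:5) {
    g <- random_genotypes(15, 8, seed = rep)
    pheno <- tibble::tibble(
      sample_id = sample(c(g$sample_ids[sample(15, 12)], "zz1", "zz2")),
      status = rep_len(c(1L, 0L), 14)
    )
    res <- align_cohort(g, pheno)
    expect_equal(res$genotypes$sample_ids, res$phenotypes$sample_id)
    expect_equal(
      res$alignment$sample_id,
      sort(intersect(g$sample_ids, pheno$sample_id))
    )
    # brute-force per-id dictionary lookup
    for (id in res$alignment$sample_id) {
      i <- which(res$alignment$sample_id == id)
      expect_equal(
        unname(res$genotypes$values[i, ]),
        unname(g$values[which(g$sample_ids == id), ])
      )
      expect_equal(
        res$phenotypes$status[i],
        pheno$status[which(pheno$sample_id == id)]
      )
    }
  }
})

test_that("identical id lists give the identity alignment", {
  g <- random_genotypes(6, 4, seed = 3)
  pheno <- tibble::tibble(sample_id = g$sample_ids, status = rep(0:1, 3))
  res <- align_cohort(g, pheno)
  expect_identical(unname(res$genotypes$values), unname(g$values))
  expect_identical(res$alignment$genotype_row, 1:6)
})

test_that("disjoint id sets are an error", {
  g <- random_genotypes(4, 3)
  pheno <- tibble::tibble(sample_id = c("x1", "x2"), status = c(1L, 0L))
  expect_error(align_cohort(g, pheno), "no shared sample ids")
})

test_that("working/validation split is stratified, covering and seeded", {
  status <- rep(c(1L, 0L), c(40, 60))
  s1 <- split_working_validation(status, 0.2, seed = 11)
  s2 <- split_working_validation(status, 0.2, seed = 11)
  expect_identical(s1, s2)
  expect_length(s1$validation, 20L)
  expect_setequal(c(s1$working, s1$validation), seq_along(status))
  expect_length(intersect(s1$working, s1$validation), 0L)
  # stratification: 8 cases of 40, 12 controls of 60
  expect_equal(sum(status[s1$validation]), 8L)

  s3 <- split_working_validation(status, 0.2, seed = 12)
  expect_false(identical(s1$validation, s3$validation))

  expect_equal(
    lengths(split_working_validation(rep(0:1, 5), 0.5, seed = 1)),
    c(working = 5L, validation = 5L)
  )
  expect_error(split_working_validation(status, 0, seed = 1), "in \\(0, 1\\)")
  expect_error(
    split_working_validation(c(1L, rep(0L, 9)), 0.5, seed = 1),
    "both classes"
  )
})
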