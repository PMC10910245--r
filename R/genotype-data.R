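#' Construct a genotype matrix object
#'
#' Bundles an additively coded dosage matrix (samples x SNPs, entries 0, 1, 2
#' or `NA` for missing genotypes) with per-SNP metadata and sample
#' identifiers. All readers, QC filters and the simulator produce this
#' container; downstream ranking and scoring consume its numeric matrix.
#'
#' @param values Integer/numeric matrix, `n_samples x n_snps`, entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row.
#' @param snps A data frame with one row per SNP column; must contain unique
#'   `id`, plus `chrom`, `pos_bp` (1-based base pairs), `ref_allele`,
#'   `alt_allele`. Dosages count copies of `alt_allele`.
#' @return An object of class `genotype_matrix`.
#' @examples
#' g <- genotype_matrix(
#'   matrix(c(0, 1, 2, 1), nrow = 2),
#'   sample_ids = c("s1", "s2"),
#'   snps = tibble::tibble(
#'     id = c("rs1", "rs2"), chrom = "1", pos_bp = c(100L, 200L),
#'     ref_allele = "A", alt_allele = "G"
#'   )
#' )
#' dim(g)
#' @export
genotype_matrix <- function(values, sample_ids, snps) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  snps <- tibble::as_tibble(snps)
  stopifnot(
    nrow(values) == length(sample_ids),
    ncol(values) == nrow(snps),
    all(c("id", "chrom", "pos_bp", "ref_allele", "alt_allele") %in% names(snps))
  )
  if (anyDuplicated(sample_ids)) stop("sample ids must be unique")
  if (anyDuplicated(snps$id)) stop("SNP ids must be unique")
  bad <- !(values %in% c(0, 1, 2)) & !is.na(values)
  if (any(bad)) stop("genotype entries must be 0, 1, 2 or NA")
  if (any(snps$pos_bp < 1)) stop("pos_bp must be >= 1")
  if (any(!nzchar(snps$ref_allele)) || any(!nzchar(snps$alt_allele))) {
    stop("alleles must be non-empty")
  }
  dimnames(values) <- list(sample_ids, snps$id)
  structure(
    list(values = values, sample_ids = as.character(sample_ids), snps = snps),
    class = "genotype_matrix"
  )
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(
    "<genotype_matrix> ", nrow(x$values), " samples x ", ncol(x$values),
    " SNPs (", sum(is.na(x$values)), " missing calls)\n",
    sep = ""
  )
  invisible(x)
}

#' Subset a genotype matrix by sample rows and/or SNP columns
#'
#' @param x A [genotype_matrix()].
#' @param i,j Row (sample) and column (SNP) indices, any form accepted by
#'   matrix subsetting.
#' @param ... Unused.
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  genotype_matrix(
    x$values[i, j, drop = FALSE],
    sample_ids = x$sample_ids[i],
    snps = x$snps[j, , drop = FALSE]
  )
}

#' Read additive-dosage genotypes from a PLINK-style .raw file
#'
#' Expects the whitespace-delimited text layout written by
#' `plink --recode A`: a header line `FID IID PAT MAT SEX PHENOTYPE` followed
#' by one column per SNP named `<id>_<counted allele>`, with dosages in
#' `{0, 1, 2}` and missing genotypes as `NA`. The counted allele is taken as
#' the alternate allele; `.raw` carries no positions, so `chrom`/`pos_bp`
#' default to `"0"`/column order unless a companion map is supplied.
#'
#' @param path Path to the `.raw` file.
#' @param map Optional data frame with columns `id`, `chrom`, `pos_bp`,
#'   `ref_allele` to fill in SNP metadata (matched by SNP id).
#' @return A [genotype_matrix()].
#' @seealso [read_ped_map()] for the allele-pair format, [write_raw()].
#' @export
read_raw <- function(path, map = NULL) {
  tab <- utils::read.table(
    path,
    header = TRUE, na.strings = c("NA", "-9"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  geno_cols <- setdiff(names(tab), fixed)
  if (!"IID" %in% names(tab)) stop("malformed .raw file: no IID column")
  snp_id <- sub("_[^_]+$", "", geno_cols)
  counted <- sub("^.*_", "", geno_cols)
  values <- as.matrix(tab[, geno_cols, drop = FALSE])
  if (any(!(values %in% c(0, 1, 2)) & !is.na(values))) {
    bad_line <- which(apply(values, 1, function(r) {
      any(!(r %in% c(0, 1, 2)) & !is.na(r))
    }))[1]
    stop("parse error in ", path, ": non-additive dosage on data line ", bad_line)
  }
  snps <- tibble::tibble(
    id = snp_id,
    chrom = "0",
    pos_bp = seq_along(snp_id),
    ref_allele = "N",
    alt_allele = counted
  )
  if (!is.null(map)) {
    map <- tibble::as_tibble(map)
    idx <- match(snps$id, map$id)
    hit <- !is.na(idx)
    snps$chrom[hit] <- as.character(map$chrom[idx[hit]])
    snps$pos_bp[hit] <- as.integer(map$pos_bp[idx[hit]])
    if ("ref_allele" %in% names(map)) {
      snps$ref_allele[hit] <- map$ref_allele[idx[hit]]
    }
  }
  genotype_matrix(values, sample_ids = as.character(tab$IID), snps = snps)
}

#' Write a genotype matrix as a PLINK-style .raw file
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_raw <- function(g, path) {
  header <- c(
    "FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE",
    paste0(g$snps$id, "_", g$snps$alt_allele)
  )
  body <- cbind(
    g$sample_ids, g$sample_ids, "0", "0", "0", "-9",
    ifelse(is.na(g$values), "NA", format(g$values, trim = TRUE, scientific = FALSE))
  )
  writeLines(
    c(paste(header, collapse = " "), apply(body, 1, paste, collapse = " ")),
    path
  )
  invisible(path)
}

valid_alleles <- c("A", "C", "G", "T")

#' Read genotypes from a PLINK 1.x text .ped/.map pair
#'
#' The `.map` file gives per-SNP metadata (chromosome, id, genetic distance,
#' base-pair position); the `.ped` file holds six leading sample columns
#' followed by two allele calls per SNP. `0` codes a missing allele. Dosages
#' count copies of the alternate allele, defined as the less frequent of the
#' two observed alleles (ties broken alphabetically). SNP records carrying a
#' haploid call (exactly one of the two alleles missing) or a non-ACGT allele
#' are excluded, counted, and reported via a message.
#'
#' @param ped_path,map_path Paths to the `.ped` and `.map` files.
#' @return A [genotype_matrix()]; the number of excluded SNP records is
#'   attached as attribute `n_excluded`.
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(
    map_path,
    col.names = c("chrom", "id", "cm", "pos_bp"),
    colClasses = c("character", "character", "numeric", "integer")
  )
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  n_expect <- 6L + 2L * nrow(map)
  widths <- lengths(fields)
  if (any(widths != n_expect)) {
    stop(
      "parse error in ", ped_path, ": line ", which(widths != n_expect)[1],
      " has ", widths[widths != n_expect][1], " fields, expected ", n_expect
    )
  }
  ped <- do.call(rbind, fields)
  sample_ids <- ped[, 2]
  a1 <- ped[, 6L + 2L * seq_len(nrow(map)) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(nrow(map)), drop = FALSE]

  keep <- logical(nrow(map))
  values <- matrix(NA_real_, nrow = length(sample_ids), ncol = nrow(map))
  ref <- alt <- character(nrow(map))
  for (j in seq_len(nrow(map))) {
    x1 <- a1[, j]
    x2 <- a2[, j]
    haploid <- xor(x1 == "0", x2 == "0")
    bad_allele <- !(x1 %in% c(valid_alleles, "0")) | !(x2 %in% c(valid_alleles, "0"))
    if (any(haploid) || any(bad_allele)) next # record rejected
    keep[j] <- TRUE
    obs <- c(x1, x2)
    obs <- obs[obs != "0"]
    freq <- sort(table(factor(obs, levels = valid_alleles)), decreasing = TRUE)
    freq <- freq[freq > 0]
    if (length(freq) == 0) {
      ref[j] <- "N"
      alt[j] <- "N"
      values[, j] <- ifelse(x1 == "0", NA_real_, 0)
      next
    }
    ref[j] <- names(freq)[1]
    alt[j] <- if (length(freq) >= 2) names(freq)[length(freq)] else names(freq)[1]
    dose <- (x1 == alt[j]) + (x2 == alt[j])
    dose[x1 == "0"] <- NA_real_
    values[, j] <- dose
  }
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(
      "read_ped_map: excluded ", n_excluded,
      " SNP record(s) with haploid or non-ACGT allele calls"
    )
  }
  snps <- tibble::tibble(
    id = map$id[keep], chrom = map$chrom[keep], pos_bp = map$pos_bp[keep],
    ref_allele = ref[keep], alt_allele = alt[keep]
  )
  out <- genotype_matrix(values[, keep, drop = FALSE], sample_ids, snps)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Read genotypes from a supported text format
#'
#' Thin dispatcher over [read_raw()] and [read_ped_map()].
#'
#' @param path Path to the `.raw` file, or to the `.ped` file when
#'   `format = "ped_map"`.
#' @param format `"raw"` or `"ped_map"`.
#' @param map_path `.map` path (defaults to `path` with its extension
#'   replaced) when `format = "ped_map"`.
#' @return A [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("raw", "ped_map"), map_path = NULL) {
  format <- match.arg(format)
  if (format == "raw") {
    read_raw(path)
  } else {
    if (is.null(map_path)) map_path <- sub("\\.ped$", ".map", path)
    read_ped_map(path, map_path)
  }
}

#' Read a phenotype table
#'
#' Reads a delimited text file (TSV or CSV, sniffed from the header line)
#' with columns `sample_id`, `status` and optional numeric covariates.
#' `status` must be binary: 1 = case, 0 = control.
#'
#' @param path Path to the phenotype file.
#' @return A tibble with `sample_id` (character), `status` (integer 0/1) and
#'   any covariate columns coerced to numeric.
#' @export
read_phenotypes <- function(path) {
  first <- readLines(path, n = 1)
  delim <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else " "
  tab <- utils::read.table(
    path,
    header = TRUE, sep = delim, stringsAsFactors = FALSE
  )
  if (!all(c("sample_id", "status") %in% names(tab))) {
    stop("phenotype file must have 'sample_id' and 'status' columns")
  }
  bad <- which(!(tab$status %in% c(0, 1)))
  if (length(bad) > 0) {
    stop(
      "non-binary status value '", tab$status[bad[1]], "' in row ", bad[1],
      " of ", path
    )
  }
  if (anyDuplicated(tab$sample_id)) stop("duplicate sample ids in ", path)
  out <- tibble::as_tibble(tab)
  out$sample_id <- as.character(out$sample_id)
  out$status <- as.integer(out$status)
  covars <- setdiff(names(out), c("sample_id", "status"))
  for (v in covars) out[[v]] <- as.numeric(out[[v]])
  out
}

#' Write a phenotype table as TSV
#'
#' @param pheno Tibble as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(
    pheno, path,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' Align genotype and phenotype data on shared sample ids
#'
#' Intersects the two sample-id sets, orders the intersection
#' lexicographically (a fixed, platform-independent ordering), and reindexes
#' both inputs so that row i of the genotypes and row i of the phenotypes
#' describe the same subject. Sample ids play no further role downstream.
#'
#' @param g A [genotype_matrix()].
#' @param pheno A phenotype tibble from [read_phenotypes()].
#' @return A list with `genotypes`, `phenotypes` (row-aligned) and
#'   `alignment`, a tibble of `sample_id`, `genotype_row`, `phenotype_row`.
#' @export
align_cohort <- function(g, pheno) {
  common <- sort(intersect(g$sample_ids, pheno$sample_id))
  if (length(common) == 0) {
    stop("no shared sample ids between genotype and phenotype data")
  }
  gi <- match(common, g$sample_ids)
  pi <- match(common, pheno$sample_id)
  list(
    genotypes = g[gi, ],
    phenotypes = pheno[pi, , drop = FALSE],
    alignment = tibble::tibble(
      sample_id = common, genotype_row = gi, phenotype_row = pi
    )
  )
}

#' Split samples into working and validation sets
#'
#' Draws a class-stratified validation set so that both parts keep the
#' cohort's case/control balance; the validation rows take no part in
#' ranking, scoring or support counting and are reserved for a single final
#' predictivity evaluation.
#'
#' @param status Integer 0/1 vector over the aligned samples.
#' @param validation_fraction Fraction of samples held out, in (0, 1).
#' @param seed Integer seed making the draw reproducible.
#' @return A list with sorted integer vectors `working` and `validation`.
#' @export
split_working_validation <- function(status, validation_fraction, seed) {
  if (!(validation_fraction > 0 && validation_fraction < 1)) {
    stop("validation_fraction must be in (0, 1)")
  }
  local_rng(seed)
  cases <- which(status == 1)
  controls <- which(status == 0)
  # largest-remainder allocation: per-class quotas rounded so the overall
  # validation count equals round(n * fraction), cases taking ties
  total <- round(length(status) * validation_fraction)
  quota <- c(length(cases), length(controls)) * validation_fraction
  base <- floor(quota)
  extra <- total - sum(base)
  if (extra > 0) {
    give <- order(quota - base, c(2, 1), decreasing = TRUE)[seq_len(extra)]
    base[give] <- base[give] + 1
  }
  n_vc <- base[1]
  n_vk <- base[2]
  if (n_vc < 1 || n_vk < 1 ||
      n_vc >= length(cases) || n_vk >= length(controls)) {
    stop("validation_fraction leaves a part without both classes")
  }
  validation <- sort(c(sample(cases, n_vc), sample(controls, n_vk)))
  list(
    working = setdiff(seq_along(status), validation),
    validation = validation
  )
}

# Seed the session RNG for the calling frame only, restoring the previous
# state on exit so library code never perturbs the user's RNG stream.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(seed)
}

# Derive a replication/stage seed from a master seed; keeps results
# reproducible while giving each stage an independent stream. Stays inside
# 32-bit integer range.
derive_seed <- function(master_seed, counter) {
  as.integer((as.double(master_seed) * 48271 + counter * 7919) %% 2147483647)
}
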