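#' Read per-sample cytosine count files into a methylome
#'
#' Accepts Bismark-coverage-style TSVs: `chrom, start, end, methylation %,
#' methylated count, unmethylated count`, optionally followed by a `context`
#' column (`CpG`/`CpH`; assumed CpG when absent). Files are unioned on
#' (chrom, pos, context); sites missing from a sample get zero coverage.
#'
#' @param paths Character vector of file paths, one per sample.
#' @param sample_ids Sample names; default basenames without extension.
#' @return A [methylome()].
#' @export
read_methylome <- function(paths, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sub("\\.[^.]*$", "", basename(paths))
  }
  stopifnot(length(paths) == length(sample_ids))
  tabs <- purrr::map2(paths, sample_ids, function(p, id) {
    x <- readr::read_tsv(p, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE)
    if (ncol(x) < 6) rlang::abort(sprintf("%s: expected >= 6 columns", p))
    names(x)[1:6] <- c("chrom", "pos", "end", "pct", "n_meth", "n_unmeth")
    x$context <- if (ncol(x) >= 7) as.character(x[[7]]) else "CpG"
    bad <- which(x$n_meth < 0 | x$n_unmeth < 0)
    if (length(bad)) {
      rlang::abort(sprintf("%s line %d: negative count", p, bad[1]))
    }
    dup <- duplicated(x[c("chrom", "pos", "context")])
    if (any(dup)) {
      rlang::abort(sprintf("%s line %d: duplicate (chrom, pos, context)",
                           p, which(dup)[1]))
    }
    tibble::tibble(chrom = as.character(x$chrom), pos = x$pos,
                   context = x$context, sample_id = id,
                   n_meth = x$n_meth, coverage = x$n_meth + x$n_unmeth)
  })
  long <- dplyr::bind_rows(tabs)
  sites <- dplyr::distinct(long, .data$chrom, .data$pos, .data$context) |>
    dplyr::arrange(.data$chrom, .data$pos)
  key <- paste(sites$chrom, sites$pos, sites$context)
  meth <- matrix(0L, nrow(sites), length(sample_ids))
  cov <- matrix(0L, nrow(sites), length(sample_ids))
  for (j in seq_along(tabs)) {
    i <- match(paste(tabs[[j]]$chrom, tabs[[j]]$pos, tabs[[j]]$context), key)
    meth[i, j] <- as.integer(tabs[[j]]$n_meth)
    cov[i, j] <- as.integer(tabs[[j]]$coverage)
  }
  methylome(dplyr::mutate(sites, strand = "*"), meth, cov, sample_ids)
}

#' Write a methylome as per-sample Bismark-coverage-style files
#'
#' Columns: chrom, pos, pos, methylation percentage, methylated count,
#' unmethylated count, context. Only covered sites are written for a sample.
#'
#' @param m A [methylome()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_bismark_cov <- function(m, dir) {
  stopifnot(inherits(m, "methylome"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(m$samples, ".cov"))
  for (j in seq_along(m$samples)) {
    keep <- m$coverage[, j] > 0
    tab <- data.frame(
      chrom = m$sites$chrom[keep], pos = m$sites$pos[keep],
      end = m$sites$pos[keep],
      pct = round(100 * m$methylated[keep, j] / m$coverage[keep, j], 4),
      n_meth = m$methylated[keep, j],
      n_unmeth = m$coverage[keep, j] - m$methylated[keep, j],
      context = m$sites$context[keep]
    )
    readr::write_tsv(tab, paths[j], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Export smoothed methylation as bedGraph, one file per sample
#'
#' @param m A smoothed [methylome()].
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_smoothed_bedgraph <- function(m, dir) {
  stopifnot(inherits(m, "methylome"))
  if (is.null(m$smoothed)) rlang::abort("methylome is not smoothed yet")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(m$samples, ".smoothed.bedGraph"))
  for (j in seq_along(m$samples)) {
    tab <- data.frame(chrom = m$sites$chrom, start = m$sites$pos - 1L,
                      end = m$sites$pos, value = round(m$smoothed[, j], 6))
    readr::write_tsv(tab, paths[j], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Read a BED3 file (0-based half-open) as a tibble
#'
#' @param path BED file path.
#' @return Tibble with chrom, start, end plus `start1`/`end1` (1-based
#'   inclusive).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 3)) {
    rlang::abort(sprintf("%s line %d: BED needs >= 3 fields",
                         path, which(nfield < 3)[1]))
  }
  chrom <- vapply(parts, `[[`, "", 1)
  start <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad)) {
    rlang::abort(sprintf("%s line %d: malformed BED interval", path, bad[1]))
  }
  conv <- bed_to_1based(start, end)
  tibble::tibble(chrom = chrom, start = start, end = end,
                 start1 = conv$start1, end1 = conv$end1)
}

#' Write intervals as BED (0-based half-open)
#'
#' @param intervals Tibble/data frame with `chrom`, `start`, `end` already in
#'   BED convention, plus optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(as.data.frame(intervals)[cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Write a genotype set as a minimal VCF v4.2 (GT field)
#'
#' @param genotypes A `genotype_set`.
#' @param path Output path (plain text).
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(genotypes, path) {
  stopifnot(inherits(genotypes, "genotype_set"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s>", unique(genotypes$snps$chrom)),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", genotypes$samples), collapse = "\t")
  ), con)
  d <- genotypes$dosage
  body <- vapply(seq_len(nrow(genotypes$snps)), function(i) {
    g <- gt_code[as.character(d[, i])]
    g[is.na(g)] <- "./."
    paste(c(genotypes$snps$chrom[i], genotypes$snps$pos[i],
            genotypes$snps$snp_id[i], "A", "G", ".", "PASS", ".", "GT", g),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read genotypes from a VCF with common-variant QC filters
#'
#' Dosage is the alternate-allele count from the GT field. SNPs are dropped
#' unless MAF > `maf_min`, missingness < `miss_max`, and the 1-df chi-square
#' Hardy-Weinberg test gives p > `hwe_p_min`. Multi-allelic records are
#' skipped with a warning.
#'
#' @param vcf_path Path to a VCF (v4.x, GT present).
#' @param maf_min,miss_max,hwe_p_min QC thresholds.
#' @return A `genotype_set`.
#' @export
read_genotypes <- function(vcf_path, maf_min = 0.05, miss_max = 0.10,
                           hwe_p_min = 1e-6) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    rlang::warn(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  alt_count <- function(g) {
    out <- rep(NA_integer_, length(g))
    clean <- gsub("|", "/", g, fixed = TRUE)
    out[clean %in% c("0/0")] <- 0L
    out[clean %in% c("0/1", "1/0")] <- 1L
    out[clean %in% c("1/1")] <- 2L
    out
  }
  dosage <- t(apply(gt, 1, alt_count))  # SNPs x samples
  samples <- colnames(gt)

  n <- length(samples)
  miss <- rowMeans(is.na(dosage))
  af <- rowMeans(dosage, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  n0 <- rowSums(dosage == 0, na.rm = TRUE)
  n1 <- rowSums(dosage == 1, na.rm = TRUE)
  n2 <- rowSums(dosage == 2, na.rm = TRUE)
  hwe <- hwe_test(n0, n1, n2)
  keep <- which(maf > maf_min & miss < miss_max & hwe > hwe_p_min)
  if (!length(keep)) rlang::warn("all SNPs removed by QC filters")

  new_genotype_set(
    snps = tibble::tibble(
      snp_id = unname(ifelse(fix[keep, "ID"] == ".",
                             paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"]),
                             fix[keep, "ID"])),
      chrom = unname(fix[keep, "CHROM"]),
      pos = as.numeric(fix[keep, "POS"]),
      maf = maf[keep], missingness = miss[keep], hwe_p = hwe[keep]
    ),
    dosage = t(dosage[keep, , drop = FALSE]),
    samples = samples
  )
}
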