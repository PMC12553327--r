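#' Read genotypes from a VCF file
#'
#' Parses biallelic records with GT fields into a [GenotypeMatrix-class].
#' Alt-allele counts (`0/0 -> 0`, `0/1 -> 1`, `1/1 -> 2`, `./.` -> missing)
#' are computed first and then oriented to the minor allele as in
#' [readPlink()]. Multi-allelic records are skipped with a warning.
#'
#' @param path path to a VCF 4.x file (plain or bgzipped).
#' @return a [GenotypeMatrix-class].
#' @export
readVcfGenotypes <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (ncol(vcf@gt) < 2 || !grepl("GT", vcf@gt[1, "FORMAT"]))
    stop("VCF has no GT field: ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped in ", path)
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  alleles <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(p) {
      p <- suppressWarnings(as.integer(p))
      if (anyNA(p)) NA_integer_ else sum(p)
    }, integer(1))
  }
  counts <- t(apply(gt, 1, alleles))
  if (ncol(gt) == 1) counts <- matrix(counts, ncol = 1)
  counts <- t(counts)  # samples x snps
  rownames(counts) <- colnames(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  variants <- data.frame(id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  .orientMinor(counts, variants)
}

#' Read GWAS summary statistics from delimited text
#'
#' @param path delimited text file with a header row.
#' @param column_map named list/character mapping the fields `id`,
#'   `effect_allele`, `beta`, `p` (optionally `se`) to column names in the
#'   file.
#' @param sep field separator (default tab).
#' @return a [SummaryStats-class]. Rows with p outside (0, 1] are dropped;
#'   the number dropped is reported in a message and attached as attribute
#'   `"n_dropped"` on the returned object's stats table.
#' @export
readSummaryStats <- function(path,
                             column_map = list(id = "SNP",
                                               effect_allele = "A1",
                                               beta = "BETA", p = "P"),
                             sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "effect_allele", "beta", "p")
  for (f in need)
    if (is.null(column_map[[f]]) || !column_map[[f]] %in% colnames(tab))
      stop("summary-statistics file lacks mapped column for '", f, "': ", path)
  p <- as.numeric(tab[[column_map[["p"]]]])
  ok <- !is.na(p) & p > 0 & p <= 1
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    message(n_dropped, " row(s) with p outside (0,1] dropped from ", path)
  se <- if (!is.null(column_map[["se"]]) &&
            column_map[["se"]] %in% colnames(tab))
    as.numeric(tab[[column_map[["se"]]]])[ok] else NA_real_
  out <- SummaryStats(id = tab[[column_map[["id"]]]][ok],
                      effect_allele = tab[[column_map[["effect_allele"]]]][ok],
                      beta = as.numeric(tab[[column_map[["beta"]]]])[ok],
                      p = p[ok], se = se)
  attr(out@stats, "n_dropped") <- n_dropped
  out
}

#' Write summary statistics as TSV
#' @param x a [SummaryStats-class].
#' @param path output path.
#' @export
writeSummaryStats <- function(x, path) {
  utils::write.table(as.data.frame(statsTable(x)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate table
#'
#' TSV with header, keyed by sample id; every column other than the id and
#' outcome columns is treated as a numeric covariate.
#'
#' @param path TSV path.
#' @param id_col,y_col names of the sample-id and binary-outcome columns.
#' @return a [PhenotypeTable-class].
#' @export
readPhenotypeTable <- function(path, id_col = "IID", y_col = "y") {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!id_col %in% colnames(tab)) stop("missing id column '", id_col, "'")
  if (!y_col %in% colnames(tab)) stop("missing outcome column '", y_col, "'")
  covs <- tab[, setdiff(colnames(tab), c(id_col, y_col)), drop = FALSE]
  PhenotypeTable(tab[[id_col]], tab[[y_col]],
                 if (ncol(covs)) as.matrix(covs) else NULL)
}

#' Write a phenotype table as TSV
#' @param x a [PhenotypeTable-class].
#' @param path output path.
#' @export
writePhenotypeTable <- function(x, path) {
  tab <- data.frame(IID = sampleIds(x), y = unname(outcome(x)),
                    check.names = FALSE)
  cv <- covariates(x)
  if (ncol(cv)) tab <- cbind(tab, as.data.frame(cv))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write per-sample scores as TSV
#' @param samples sample ids.
#' @param scores numeric scores.
#' @param path output path.
#' @export
writeScores <- function(samples, scores, path) {
  utils::write.table(data.frame(IID = samples, GRS = scores), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize target genotypes with base summary statistics
#'
#' Intersects on SNP id and aligns the base effect allele to the target's
#' minor (counted) allele: when the base effect allele equals the target's
#' major allele the beta sign is flipped (p unchanged); SNPs whose effect
#' allele matches neither target allele are dropped and counted. Matching
#' is by id only — no strand-flip inference is attempted.
#'
#' @param target a [GenotypeMatrix-class].
#' @param base a [SummaryStats-class].
#' @return list with elements `target` (GenotypeMatrix restricted to the
#'   intersection), `base` (SummaryStats aligned to it, same SNP order),
#'   `n_flipped` and `n_dropped`.
#' @export
harmonize <- function(target, base) {
  if (nSnps(target) == 0 || nrow(statsTable(base)) == 0)
    stop("harmonize needs non-empty target and base inputs")
  v <- variantInfo(target)
  s <- statsTable(base)
  shared <- intersect(v$id, s$id)
  if (!length(shared)) stop("no shared SNP ids between target and base")
  vi <- match(shared, v$id)
  si <- match(shared, s$id)
  ea <- s$effect_allele[si]
  keep_as_is <- ea == v$alt[vi]
  flip <- ea == v$ref[vi]
  drop <- !(keep_as_is | flip)
  n_dropped <- sum(drop)
  sel <- which(!drop)
  if (!length(sel)) stop("no allele-matchable SNPs between target and base")
  beta <- s$beta[si]
  beta[flip] <- -beta[flip]
  stats <- DataFrame(id = shared, effect_allele = v$alt[vi],
                     beta = beta, se = s$se[si], p = s$p[si], z = s$z[si],
                     flag = s$flag[si])[sel, , drop = FALSE]
  list(target = target[, vi[sel]],
       base = new("SummaryStats", stats = stats),
       n_flipped = sum(flip), n_dropped = n_dropped)
}
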