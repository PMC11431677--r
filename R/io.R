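#' Write / read replicate genotype files
#'
#' One CSV per replicate (rows = individuals, columns = 1-based locus ids,
#' values 0/1/2 dosages) plus a JSON manifest recording the configuration,
#' seed, locus ids and file list, sufficient to reproduce the run.
#'
#' @param reps A [ReplicateSet-class].
#' @param dir Output directory (created if missing).
#' @param seed Optional seed to record in the manifest.
#' @return \code{writeGenotypes}: the manifest path, invisibly.
#'   \code{readGenotypes}: a [ReplicateSet-class] (with no pool).
#' @export
writeGenotypes <- function(reps, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("replicate_%03d.csv", seq_along(reps@samples))
  for (k in seq_along(reps@samples)) {
    utils::write.csv(as.data.frame(reps@samples[[k]]),
                     file.path(dir, files[k]), row.names = FALSE)
  }
  cfg <- reps@config
  manifest <- list(
    package = "ldentropy",
    version = as.character(utils::packageVersion("ldentropy")),
    config = list(
      ne = if (isInfiniteNe(cfg)) "inf" else cfg@ne, s = cfg@s, l = cfg@l,
      generations = cfg@generations, nRep = cfg@nRep,
      filterScope = cfg@filterScope, p = cfg@p
    ),
    seed = seed,
    locusIds = reps@locusIds,
    files = files
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeGenotypes
#' @export
readGenotypes <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- manifest$config
  config <- simConfig(ne = if (identical(cfg$ne, "inf")) Inf else cfg$ne,
                      s = cfg$s, l = cfg$l, generations = cfg$generations,
                      nRep = cfg$nRep, filterScope = cfg$filterScope,
                      p = cfg$p)
  smp <- lapply(manifest$files, function(f) {
    m <- as.matrix(utils::read.csv(file.path(dir, f), check.names = FALSE))
    storage.mode(m) <- "integer"
    m
  })
  new("ReplicateSet", samples = smp, locusIds = manifest$locusIds,
      pool = NULL, config = config)
}

#' Write / read the long-format r-squared table
#'
#' Upper triangle only, one row per (replicate, locus pair): columns
#' \code{replicate}, \code{locus_i}, \code{locus_j} (1-based), \code{r2}.
#'
#' @param arr An [R2ReplicateArray-class].
#' @param path CSV path.
#' @return \code{writeR2Table}: \code{path}, invisibly.
#'   \code{readR2Table}: an [R2ReplicateArray-class].
#' @export
writeR2Table <- function(arr, path) {
  v <- arr@values
  l <- dim(v)[1]; n <- dim(v)[3]
  idx <- makePairIndex(l)
  lin <- (idx@pairs[, 2] - 1L) * l + idx@pairs[, 1]
  flat <- matrix(v, nrow = l * l)[lin, , drop = FALSE]
  df <- data.frame(
    replicate = rep(seq_len(n), each = nrow(idx@pairs)),
    locus_i = rep(idx@pairs[, 1], times = n),
    locus_j = rep(idx@pairs[, 2], times = n),
    # 17 significant digits: the write -> read round trip is lossless
    r2 = sprintf("%.17g", as.vector(flat))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeR2Table
#' @export
readR2Table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("replicate", "locus_i", "locus_j", "r2")
  if (!all(need %in% names(df)))
    stop("r-squared table must have columns ", paste(need, collapse = ", "))
  l <- max(df$locus_j)
  repIds <- sort(unique(df$replicate))
  v <- array(0, dim = c(l, l, length(repIds)))
  for (k in seq_along(repIds)) {
    s <- diag(nrow = l)
    sub <- df[df$replicate == repIds[k], , drop = FALSE]
    s[cbind(sub$locus_i, sub$locus_j)] <- sub$r2
    s[cbind(sub$locus_j, sub$locus_i)] <- sub$r2
    v[, , k] <- s
  }
  ids <- locusNames(l)
  dimnames(v) <- list(ids, ids, paste0("rep", repIds))
  new("R2ReplicateArray", values = v, locusIds = ids,
      replicateIds = paste0("rep", repIds))
}

#' Minimal VCF export / import of a genotype sample
#'
#' Exports one dosage matrix as a GT-only VCF on a single pseudo-contig
#' with positions 1..L; the loci are unlinked by construction, so the
#' coordinates are labels, not physical positions. Dosage counts copies of
#' the REF allele: 2 -> 0/0, 1 -> 0/1, 0 -> 1/1. Import requires the
#' \pkg{vcfR} package.
#'
#' @param genotypes Integer dosage matrix (individuals x loci).
#' @param path Output \code{.vcf} path.
#' @return \code{writeVcfGenotypes}: \code{path}, invisibly.
#'   \code{readVcfGenotypes}: an integer dosage matrix.
#' @export
writeVcfGenotypes <- function(genotypes, path) {
  l <- ncol(genotypes)
  ids <- colnames(genotypes)
  if (is.null(ids)) ids <- locusNames(l)
  gtChar <- c("1/1", "0/1", "0/0")[genotypes + 1L]
  gt <- matrix(gtChar, nrow = nrow(genotypes))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=ldentropy",
    sprintf("##contig=<ID=pseudo1,length=%d>", l),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("ind", seq_len(nrow(genotypes)))),
          collapse = "\t")
  )
  body <- vapply(seq_len(l), function(j) {
    paste(c("pseudo1", j, ids[j], "A", "T", ".", "PASS", ".", "GT",
            gt[, j]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeVcfGenotypes
#' @export
readVcfGenotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("VCF import requires the 'vcfR' package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf)
  dos <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                dimnames = list(colnames(gt), rownames(gt)))
  lut <- c("0/0" = 2L, "0|0" = 2L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 0L, "1|1" = 0L)
  for (j in seq_len(nrow(gt))) dos[, j] <- lut[gt[j, ]]
  if (anyNA(dos)) stop("unsupported genotype codes in VCF (need biallelic diploid GT)")
  dos
}

#' Read a flat key = value configuration file
#'
#' One \code{key: value} or \code{key = value} per line (a YAML-compatible
#' subset), keys mirroring [simConfig()] arguments; \code{ne} may be
#' \code{inf}, and grid keys may hold comma-separated level lists
#' (e.g. \code{l: 25,50,100,200}). Blank lines and \code{#} comments are
#' ignored. Scalar numbers are returned numeric; anything else (including
#' comma-separated lists) is returned as a string for the caller to split.
#'
#' @param path Config file path.
#' @return A named list of parsed values.
#' @export
readConfigFile <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  kv <- strsplit(lines, "[:=]")
  vals <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  names(vals) <- vapply(kv, function(p) trimws(p[1]), character(1))
  if (!is.null(vals$ne) && is.character(vals$ne) &&
      tolower(vals$ne) %in% c("inf", "infinite")) vals$ne <- Inf
  vals
}
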