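# Containers and file formats.
#
# On-disk dialects (all plain text, tab separated):
#   * beta matrix: probes as rows (array-export convention), first column
#     `probe_id`, remaining columns one per sample; transposed to
#     samples x probes in memory.
#   * probe annotation: probe_id, chrom, pos (1-based), optional gene.
#   * dosage matrix: variant rows: variant_id, chrom, pos, ref, alt, then
#     one dosage column per sample. A VCF with DS or GT fields is also
#     accepted (DS preferred, GT summed to dosage).
#   * sample table: sample_id, status (0/1/NA), age, institution,
#     cycle_phase, ancestry.
#   * score weights: feature_id, [effect_allele], weight; '#' comments.
#   * relationship matrix: GCTA-style lower-triangle triplets
#     (i, j, n_features, value) in <prefix>.grm.txt plus ids in
#     <prefix>.grm.id.
# Readers reject malformed values rather than silently coercing.

#' Methylation matrix container
#'
#' @param beta numeric samples x probes matrix with values in \[0,1\] and
#'   both dimnames set; no missing values (post-QC contract).
#' @param annotation data frame with columns probe_id, chrom, pos and
#'   optionally gene; one row per probe, in probe order.
#' @return object of class `meth_matrix` (list with `beta`, `annotation`).
#' @export
meth_matrix <- function(beta, annotation) {
  .assert(is.matrix(beta) && is.numeric(beta), "beta must be a numeric matrix")
  .assert(!is.null(rownames(beta)) && !is.null(colnames(beta)),
          "beta must carry sample and probe ids as dimnames")
  .assert(!anyDuplicated(rownames(beta)) && !anyDuplicated(colnames(beta)),
          "sample and probe ids must be unique")
  .assert(!anyNA(beta), "beta matrix contains missing values")
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("beta values outside [0,1] for probe(s): ",
         paste(unique(colnames(beta)[bad[, 2]]), collapse = ", "), call. = FALSE)
  .assert(all(c("probe_id", "chrom", "pos") %in% names(annotation)),
          "annotation must have columns probe_id, chrom, pos")
  .assert(identical(annotation$probe_id, colnames(beta)),
          "annotation rows must match beta probe columns in order")
  structure(list(beta = beta, annotation = annotation), class = "meth_matrix")
}

#' Genotype dosage container
#'
#' @param dosage numeric samples x variants matrix with values in \[0,2\].
#' @param variants data frame with columns variant_id, chrom, pos, ref, alt.
#' @param maf_warn warn if any variant has MAF < 0.05 (upstream QC contract).
#' @return object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, variants, maf_warn = TRUE) {
  .assert(is.matrix(dosage) && is.numeric(dosage), "dosage must be a numeric matrix")
  .assert(!is.null(rownames(dosage)) && !is.null(colnames(dosage)),
          "dosage must carry sample and variant ids as dimnames")
  .assert(all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants)),
          "variants must have columns variant_id, chrom, pos, ref, alt")
  .assert(identical(variants$variant_id, colnames(dosage)),
          "variants rows must match dosage columns in order")
  .assert(all(variants$ref %in% c("A", "C", "G", "T")) &&
            all(variants$alt %in% c("A", "C", "G", "T")),
          "allele characters must be one of A, C, G, T")
  .assert(all(dosage >= 0 & dosage <= 2, na.rm = TRUE), "dosages must lie in [0,2]")
  if (maf_warn && nrow(dosage) > 0) {
    af <- colMeans(dosage, na.rm = TRUE) / 2
    mafs <- pmin(af, 1 - af)
    if (any(mafs < 0.05))
      warning(sum(mafs < 0.05), " variant(s) with realized MAF < 0.05 ",
              "(upstream QC contract)", call. = FALSE)
  }
  structure(list(dosage = dosage, variants = variants), class = "geno_matrix")
}

#' Score weight container
#'
#' @param df data frame with columns feature_id, weight, and (for variant
#'   weights) effect_allele.
#' @param source tag recording how the weights were derived
#'   (MOA/MOMENT/BLUP/external).
#' @param threshold the p-value selection threshold used, if any.
#' @return object of class `effect_weights` (the data frame with attributes).
#' @export
effect_weights <- function(df, source = "external", threshold = NA_real_) {
  .assert(all(c("feature_id", "weight") %in% names(df)),
          "weights need feature_id and weight columns")
  .assert(!anyDuplicated(df$feature_id), "duplicate feature_id in weights")
  .assert(is.numeric(df$weight) && all(is.finite(df$weight)),
          "weights must be finite numerics")
  structure(df, source = source, threshold = threshold,
            class = c("effect_weights", "data.frame"))
}

# cohort reading --------------------------------------------------------

.read_tsv <- function(path, ...) {
  .assert(file.exists(path), "file not found: %s", path)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             check.names = FALSE, comment.char = "#", ...)
}

#' Read a beta matrix (probes as rows on disk)
#' @param beta_path path to the beta TSV.
#' @return numeric samples x probes matrix.
#' @export
read_beta_matrix <- function(beta_path) {
  d <- .read_tsv(beta_path)
  .assert(names(d)[1] == "probe_id", "beta file must start with a probe_id column")
  mat <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(mat) <- d$probe_id
  storage.mode(mat) <- "double"
  mat
}

#' Read a sample table
#' @param sample_path path to the sample TSV.
#' @export
read_sample_table <- function(sample_path) {
  d <- .read_tsv(sample_path)
  .assert(all(c("sample_id", "status") %in% names(d)),
          "sample table needs sample_id and status columns")
  .assert(all(d$status %in% c(0L, 1L) | is.na(d$status)),
          "status must be 0, 1 or missing (unknown)")
  d
}

#' Read genotype dosages from a dosage TSV or a VCF
#'
#' For VCF input the DS FORMAT field is preferred; GT is summed to a dosage
#' when DS is absent. Missing dosages are mean-imputed per variant with a
#' message reporting the count.
#'
#' @param genotype_path path to a `.vcf` file or a dosage TSV.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(genotype_path) {
  if (grepl("\\.vcf(\\.gz)?$", genotype_path)) {
    return(.read_vcf_dosages(genotype_path))
  }
  d <- .read_tsv(genotype_path)
  meta_cols <- c("variant_id", "chrom", "pos", "ref", "alt")
  .assert(all(meta_cols %in% names(d)), "dosage file needs columns %s",
          paste(meta_cols, collapse = ", "))
  dos <- t(as.matrix(d[, setdiff(names(d), meta_cols), drop = FALSE]))
  colnames(dos) <- d$variant_id
  storage.mode(dos) <- "double"
  dos <- .impute_dosages(dos)
  geno_matrix(dos, d[, meta_cols])
}

.read_vcf_dosages <- function(path) {
  .assert(requireNamespace("vcfR", quietly = TRUE),
          "reading VCF genotypes requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  has_ds <- any(grepl("DS", v@gt[, "FORMAT"]))
  if (has_ds) {
    dos <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
  } else {
    gt <- vcfR::extract.gt(v, element = "GT")
    dos <- apply(gt, c(1, 2), function(g) {
      if (is.na(g)) return(NA_real_)
      sum(as.numeric(strsplit(g, "[/|]")[[1]]))
    })
  }
  dos <- t(dos)  # vcfR gives variants x samples
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  colnames(dos) <- ids
  dos <- .impute_dosages(dos)
  geno_matrix(dos, data.frame(variant_id = ids, chrom = fix[, "CHROM"],
                              pos = as.integer(fix[, "POS"]), ref = fix[, "REF"],
                              alt = fix[, "ALT"], stringsAsFactors = FALSE))
}

.impute_dosages <- function(dos) {
  n_missing <- sum(is.na(dos))
  if (n_missing > 0) {
    message(n_missing, " missing dosage value(s) mean-imputed per variant")
    for (j in which(colSums(is.na(dos)) > 0)) {
      mj <- mean(dos[, j], na.rm = TRUE)
      dos[is.na(dos[, j]), j] <- mj
    }
  }
  dos
}

#' Load a cohort from its file bundle
#'
#' Reads the beta matrix, genotypes, sample table and probe annotation, and
#' restricts all matrices to the intersection of sample ids, ordered as in
#' the sample table. Downstream modules rely on this positional alignment.
#'
#' @param beta_path,genotype_path,sample_path,annotation_path file paths.
#' @return list with elements `meth`, `geno`, `samples`.
#' @export
load_cohort <- function(beta_path, genotype_path, sample_path, annotation_path) {
  beta <- read_beta_matrix(beta_path)
  geno <- read_genotypes(genotype_path)
  samples <- read_sample_table(sample_path)
  ann <- .read_tsv(annotation_path)
  .assert(all(c("probe_id", "chrom", "pos") %in% names(ann)),
          "annotation needs probe_id, chrom, pos columns")
  ann <- ann[match(colnames(beta), ann$probe_id), , drop = FALSE]
  .assert(!anyNA(ann$probe_id), "annotation missing probes present in beta matrix")

  keep <- Reduce(intersect, list(samples$sample_id, rownames(beta),
                                 rownames(geno$dosage)))
  .assert(length(keep) > 0, "no samples shared between beta, genotype and sample files")
  dropped <- length(unique(c(samples$sample_id, rownames(beta),
                             rownames(geno$dosage)))) - length(keep)
  if (dropped > 0)
    warning(dropped, " sample(s) dropped: not present in all inputs", call. = FALSE)
  message(sprintf("cohort loaded: %d samples kept, %d dropped", length(keep), dropped))

  samples <- samples[samples$sample_id %in% keep, , drop = FALSE]
  ord <- samples$sample_id
  list(meth = meth_matrix(beta[ord, , drop = FALSE], ann),
       geno = geno_matrix(geno$dosage[ord, , drop = FALSE], geno$variants),
       samples = samples)
}

#' Write a simulated cohort as its file bundle
#'
#' Emits beta TSV, probe annotation TSV, dosage TSV, VCF (DS field), sample
#' TSV, and a JSON ground-truth sidecar into `dir`.
#'
#' @param cohort an `mrs_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(beta = file.path(dir, "beta.tsv"),
             annotation = file.path(dir, "annotation.tsv"),
             dosage = file.path(dir, "dosage.tsv"),
             vcf = file.path(dir, "genotypes.vcf"),
             samples = file.path(dir, "samples.tsv"),
             truth = file.path(dir, "truth.json"))

  bd <- data.frame(probe_id = colnames(cohort$meth$beta),
                   t(cohort$meth$beta), check.names = FALSE)
  write.table(bd, paths["beta"], sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$meth$annotation, paths["annotation"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  gd <- data.frame(cohort$geno$variants, t(cohort$geno$dosage), check.names = FALSE)
  write.table(gd, paths["dosage"], sep = "\t", quote = FALSE, row.names = FALSE)
  .write_vcf(cohort$geno, paths["vcf"])
  write.table(cohort$samples, paths["samples"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  truth <- cohort$truth
  truth$batch_offsets <- NULL  # dense matrix; regenerate from params if needed
  jsonlite::write_json(truth, paths["truth"], digits = NA, dataframe = "columns")
  invisible(paths)
}

.write_vcf <- function(geno, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$dosage)), collapse = "\t")),
             con)
  v <- geno$variants
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$variant_id[i], v$ref[i], v$alt[i], ".",
            "PASS", ".", "DS", format(geno$dosage[, i], trim = TRUE)),
          collapse = "\t")
  }, character(1))
  writeLines(body, con)
}

# score weights ---------------------------------------------------------

#' Read a score-weight file
#'
#' Expects a TSV with header `feature_id`, optional `effect_allele`, and
#' `weight`. Duplicate feature ids and non-numeric weights are fatal (the
#' offending line is named).
#'
#' @param path weight file path.
#' @return an [effect_weights()] object.
#' @export
read_score_weights <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  .assert(length(body) >= 1, "weight file has no header")
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  .assert("feature_id" %in% header && "weight" %in% header,
          "weight file header must contain feature_id and weight")
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  wcol <- which(header == "weight")
  vals <- vapply(seq_along(rows), function(i) {
    x <- suppressWarnings(as.numeric(rows[[i]][wcol]))
    if (is.na(x))
      stop(sprintf("non-numeric weight '%s' at line %d of %s",
                   rows[[i]][wcol], i + 1 + length(meta), path), call. = FALSE)
    x
  }, numeric(1))
  df <- data.frame(feature_id = vapply(rows, `[`, character(1), which(header == "feature_id")),
                   weight = vals, stringsAsFactors = FALSE)
  if ("effect_allele" %in% header)
    df$effect_allele <- vapply(rows, `[`, character(1), which(header == "effect_allele"))
  df <- df[, intersect(c("feature_id", "effect_allele", "weight"), names(df))]
  src <- sub("^# *source: *", "", grep("^# *source:", meta, value = TRUE))
  effect_weights(df, source = if (length(src)) src else "external")
}

#' Write a score-weight file
#' @param weights an [effect_weights()] object.
#' @param path output path.
#' @export
write_score_weights <- function(weights, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", attr(weights, "source")), con)
  thr <- attr(weights, "threshold")
  if (!is.na(thr)) writeLines(sprintf("# threshold: %g", thr), con)
  writeLines(sprintf("# n_probes: %d", nrow(weights)), con)
  write.table(as.data.frame(weights), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# relationship matrix ---------------------------------------------------

#' Write a relationship matrix as GCTA-style text triplets
#'
#' Produces `<prefix>.grm.txt` with lower-triangle lines
#' `i j n_features value` and `<prefix>.grm.id` with one sample id per line.
#'
#' @param rm a [relationship_matrix] (see [compute_relationship_matrix()]).
#' @param prefix output path prefix.
#' @export
write_relationship_matrix <- function(rm, prefix) {
  n <- length(rm$sample_ids)
  ij <- which(lower.tri(rm$values, diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE]
  lines <- sprintf("%d\t%d\t%d\t%.10g", ij[, 1], ij[, 2], rm$n_features,
                   rm$values[ij])
  writeLines(lines, paste0(prefix, ".grm.txt"))
  writeLines(rm$sample_ids, paste0(prefix, ".grm.id"))
  invisible(prefix)
}

#' Read a relationship matrix written by [write_relationship_matrix()]
#' @param prefix path prefix used at write time.
#' @param kind matrix kind label ("ORM" or "GRM").
#' @export
read_relationship_matrix <- function(prefix, kind = "ORM") {
  ids <- readLines(paste0(prefix, ".grm.id"))
  n <- length(ids)
  tri <- read.table(paste0(prefix, ".grm.txt"), sep = "\t",
                    col.names = c("i", "j", "m", "value"))
  expected <- n * (n + 1) / 2
  .assert(nrow(tri) == expected,
          "truncated relationship matrix: expected %d triplet lines, found %d",
          expected, nrow(tri))
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(tri$i, tri$j)] <- tri$value
  A[cbind(tri$j, tri$i)] <- tri$value
  structure(list(values = A, sample_ids = ids, kind = kind,
                 n_features = tri$m[1]), class = "relationship_matrix")
}

# results table ---------------------------------------------------------

#' Write the long-format evaluation results table
#'
#' Fixed columns: test_set, method, threshold, n_probes, model (MRS,
#' MRS+PRS, PRS), AUC, ci_low, ci_high, p_mrs, p_prs. AUC and CI bounds are
#' written with 4 decimals.
#'
#' @param results data frame of evaluation rows.
#' @param path output path.
#' @export
write_results_table <- function(results, path) {
  .assert(nrow(results) > 0, "results table is empty")
  cols <- c("test_set", "method", "threshold", "n_probes", "model", "AUC",
            "ci_low", "ci_high", "p_mrs", "p_prs")
  .assert(all(cols %in% names(results)), "results missing required columns")
  out <- results[, cols]
  for (cc in c("AUC", "ci_low", "ci_high"))
    out[[cc]] <- sprintf("%.4f", out[[cc]])
  for (cc in c("p_mrs", "p_prs"))
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.6g", out[[cc]]))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
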