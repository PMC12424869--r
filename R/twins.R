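# Twin-based heritability: identifying monozygotic twins and
# parent-offspring trios from kinship records, per-variant cross-twin
# Spearman correlation as the heritability estimate, the read-depth
# confound on that estimate, and the heritable-variant linkage matrix.

#' Identify monozygotic twin pairs from kinship records
#'
#' Pairs with kinship strictly above the threshold are called monozygotic.
#' Because relatedness tables can list a participant in several pairs, each
#' participant is used at most once, assigned greedily by descending
#' kinship.
#'
#' @param records data frame with columns `id_a`, `id_b`, `kinship`.
#' @param threshold MZ kinship threshold (default 0.4, strict `>`).
#' @return data frame `id_a`, `id_b`, `kinship` of deduplicated MZ pairs.
#' @export
identify_twins <- function(records, threshold = 0.4) {
  mz <- records[records$kinship > threshold, , drop = FALSE]
  mz <- mz[order(-mz$kinship, mz$id_a, mz$id_b), , drop = FALSE]
  used <- character(); keep <- logical(nrow(mz))
  for (i in seq_len(nrow(mz))) {
    if (!(mz$id_a[i] %in% used) && !(mz$id_b[i] %in% used)) {
      keep[i] <- TRUE
      used <- c(used, mz$id_a[i], mz$id_b[i])
    }
  }
  out <- mz[keep, c("id_a", "id_b", "kinship"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Identify parent-offspring pairs and trios
#'
#' A pair is parent-offspring (PO) when kinship lies in
#' `[kinship_min, kinship_max]` (bounds inclusive) and birth years differ by
#' more than `min_year_gap` years. A trio is a child with two distinct
#' parents (both older by more than the gap) that are not PO with each
#' other. Pairs with a missing birth year are skipped and logged.
#'
#' @param records data frame with `id_a`, `id_b`, `kinship`,
#'   `birth_year_a`, `birth_year_b`.
#' @param kinship_min,kinship_max PO kinship bounds (defaults 0.17, 0.35).
#' @param min_year_gap minimum birth-year difference (default 18, strict `>`).
#' @return list with `pairs` (data frame `parent_id`, `child_id`,
#'   `kinship`), `trios` (data frame `child_id`, `parent1_id`,
#'   `parent2_id`), and `skipped` (pair rows lacking birth years).
#' @export
identify_parent_offspring <- function(records, kinship_min = 0.17,
                                      kinship_max = 0.35,
                                      min_year_gap = 18) {
  k_ok <- records$kinship >= kinship_min & records$kinship <= kinship_max
  cand <- records[k_ok, , drop = FALSE]
  no_year <- is.na(cand$birth_year_a) | is.na(cand$birth_year_b)
  skipped <- cand[no_year, , drop = FALSE]
  if (nrow(skipped))
    message(nrow(skipped), " candidate PO pair(s) skipped: missing birth year")
  cand <- cand[!no_year, , drop = FALSE]
  gap_ok <- abs(cand$birth_year_a - cand$birth_year_b) > min_year_gap
  po <- cand[gap_ok, , drop = FALSE]
  # orient: parent is the earlier birth year
  parent_first <- po$birth_year_a < po$birth_year_b
  pairs <- data.frame(
    parent_id = ifelse(parent_first, po$id_a, po$id_b),
    child_id = ifelse(parent_first, po$id_b, po$id_a),
    kinship = po$kinship, stringsAsFactors = FALSE)
  po_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  po_set <- po_key(pairs$parent_id, pairs$child_id)
  trios <- list()
  for (child in unique(pairs$child_id)) {
    parents <- sort(unique(pairs$parent_id[pairs$child_id == child]))
    if (length(parents) < 2L) next
    for (i in seq_len(length(parents) - 1L)) {
      for (j in (i + 1L):length(parents)) {
        if (!po_key(parents[i], parents[j]) %in% po_set) {
          trios[[length(trios) + 1L]] <- data.frame(
            child_id = child, parent1_id = parents[i],
            parent2_id = parents[j], stringsAsFactors = FALSE)
        }
      }
    }
  }
  trios <- if (length(trios)) do.call(rbind, trios) else
    data.frame(child_id = character(), parent1_id = character(),
               parent2_id = character(), stringsAsFactors = FALSE)
  list(pairs = pairs, trios = trios, skipped = skipped)
}

#' Per-variant cross-twin correlation (heritability estimate)
#'
#' For each variant, the Spearman correlation of frequencies between the
#' two members of each MZ pair, over pairs where both values are
#' non-missing. Pair orientation (which twin is "first") is randomized once
#' per run under the given seed so column ordering in the input cannot
#' create artefacts; the estimate is orientation-symmetric in expectation
#' and the seed is recorded in the output attributes.
#'
#' @param freq matrix participants x variant keys (e.g. `vft$freq`).
#' @param pairs MZ pairs from [identify_twins()].
#' @param heritable_threshold Spearman threshold above which a variant is
#'   flagged heritable (default 0.8, strict `>`).
#' @param depth optional matrix participants x keys of reads supporting
#'   each variant, used to report mean depth among twins.
#' @param min_pairs minimum informative pairs for a defined estimate.
#' @param seed seed for the orientation randomization.
#' @return data frame `key`, `twin_spearman`, `n_pairs`, `mean_depth`,
#'   `heritable`.
#' @export
twin_variant_correlation <- function(freq, pairs, heritable_threshold = 0.8,
                                     depth = NULL, min_pairs = 3L,
                                     seed = 1L) {
  missing_ids <- setdiff(c(pairs$id_a, pairs$id_b), rownames(freq))
  if (length(missing_ids))
    stop("twin ids absent from frequency table: ",
         paste(utils::head(missing_ids), collapse = ", "))
  flip <- with_seed_local(seed, runif(nrow(pairs)) < 0.5)
  first <- ifelse(flip, pairs$id_b, pairs$id_a)
  second <- ifelse(flip, pairs$id_a, pairs$id_b)
  twin_ids <- unique(c(first, second))
  out <- lapply(colnames(freq), function(kk) {
    x <- freq[first, kk]; y <- freq[second, kk]
    ok <- !is.na(x) & !is.na(y)
    n <- sum(ok)
    r <- if (n >= min_pairs)
      suppressWarnings(stats::cor(x[ok], y[ok], method = "spearman")) else
      NA_real_
    md <- if (!is.null(depth)) mean(depth[twin_ids, kk]) else NA_real_
    data.frame(key = kk, twin_spearman = r, n_pairs = n, mean_depth = md,
               heritable = !is.na(r) & r > heritable_threshold,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "orientation_seed") <- seed
  res
}

#' Depth confound on the twin-correlation heritability estimate
#'
#' Pearson correlation between per-variant mean read depth and the
#' twin-correlation, computed over all variants and again after removing
#' low-depth variants; a drop after filtering indicates that part of the
#' apparent non-heritability is depth-driven noise.
#'
#' @param records output of [twin_variant_correlation()] (needs
#'   `mean_depth`).
#' @param depth_threshold depth filter (default 5000; filtered stratum
#'   keeps `mean_depth >= depth_threshold`).
#' @return list `r_all`, `n_all`, `r_filtered`, `n_filtered` (missing
#'   value, not an error, when a stratum has fewer than 3 variants).
#' @export
depth_confound <- function(records, depth_threshold = 5000) {
  ok <- !is.na(records$twin_spearman) & !is.na(records$mean_depth)
  all_r <- records[ok, , drop = FALSE]
  filt <- all_r[all_r$mean_depth >= depth_threshold, , drop = FALSE]
  safe_cor <- function(d)
    if (nrow(d) >= 3L) stats::cor(d$mean_depth, d$twin_spearman) else NA_real_
  list(r_all = safe_cor(all_r), n_all = nrow(all_r),
       r_filtered = safe_cor(filt), n_filtered = nrow(filt))
}

#' Linkage matrix of heritable variants
#'
#' Pairwise Pearson correlation of variant frequencies across the cohort
#' (pairwise-complete observations), annotated with each variant's region
#' and a hierarchical-clustering leaf order for heatmap plotting. Constant
#' columns yield missing correlations and are reported.
#'
#' @param freq matrix participants x variant keys.
#' @param keys heritable variant keys (at least 2).
#' @param variant_region optional named vector key -> region id.
#' @return list `correlation` (symmetric matrix, unit diagonal),
#'   `region` (annotation vector), `leaf_order`, `constant_keys`.
#' @export
heritable_linkage <- function(freq, keys, variant_region = NULL) {
  if (length(keys) < 2L) stop("need at least 2 heritable variants")
  sub <- freq[, keys, drop = FALSE]
  if (nrow(sub) < 3L) stop("need at least 3 participants")
  constant <- colnames(sub)[apply(sub, 2L, function(x)
    stats::sd(x, na.rm = TRUE) == 0 || all(is.na(x)))]
  if (length(constant))
    message("constant column(s), correlations undefined: ",
            paste(constant, collapse = ", "))
  cm <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  ord <- keys
  cc <- cm
  cc[is.na(cc)] <- 0
  if (ncol(cm) > 2L) {
    hc <- stats::hclust(stats::as.dist(1 - cc))
    ord <- colnames(cm)[hc$order]
  }
  list(correlation = cm,
       region = if (is.null(variant_region)) NULL else
         variant_region[keys],
       leaf_order = ord, constant_keys = constant)
}

#' Per-variant correlation with rDNA copy number
#'
#' @param freq matrix participants x variant keys.
#' @param c45S named numeric vector of copy numbers (names = participants).
#' @param heritable optional named logical vector for the stratified
#'   summary.
#' @return data frame `key`, `r_copy_number`, plus attribute `summary`
#'   with per-stratum mean absolute correlation when `heritable` is given.
#' @export
copy_number_correlation <- function(freq, c45S, heritable = NULL) {
  ids <- intersect(rownames(freq), names(c45S))
  if (length(ids) < 3L) stop("need at least 3 participants")
  cn <- c45S[ids]
  r <- vapply(colnames(freq), function(kk) {
    x <- freq[ids, kk]
    ok <- !is.na(x)
    if (sum(ok) < 3L || stats::sd(x[ok]) == 0 || stats::sd(cn[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], cn[ok])
  }, 1)
  out <- data.frame(key = colnames(freq), r_copy_number = unname(r),
                    stringsAsFactors = FALSE)
  if (!is.null(heritable)) {
    h <- heritable[out$key]
    attr(out, "summary") <- data.frame(
      heritable = c(TRUE, FALSE),
      mean_abs_r = c(mean(abs(out$r_copy_number[h %in% TRUE]), na.rm = TRUE),
                     mean(abs(out$r_copy_number[h %in% FALSE]), na.rm = TRUE)))
  }
  out
}

#' Read a kinship TSV (id_a, id_b, kinship, birth_year_a, birth_year_b)
#' @param path TSV path.
#' @return data frame.
#' @export
read_kinship_tsv <- function(path) {
  df <- read_tsv_commented(path)
  need <- c("id_a", "id_b", "kinship")
  if (!all(need %in% names(df)))
    stop("kinship table needs columns: ", paste(need, collapse = ", "))
  df
}
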