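# Segment-level rare-variant burden: unique-mapper counting, cohort-wide
# allele-support filtering, collapsing of indistinguishable alleles onto a
# retained representative, depth QC, copy-number-scaled zeroing of
# low-frequency alleles, renormalization, and the per-region
# Major-Allele-Frequency (MAF) statistic with burden = 1 - MAF.

#' Unique-mapper allele counts for one participant
#'
#' Counts only reads whose perfect hits touch exactly one allele across all
#' regions (the unique mappers); multi-mappers and unmapped reads contribute
#' nothing.
#'
#' @param hits hits data frame (quality-masked perfect hits recommended).
#' @return data frame `region_id`, `allele_id`, `count` (integer).
#' @export
unique_mapper_counts <- function(hits) {
  cnt <- count_alleles(hits, policy = "unique_only")
  cnt$count <- as.integer(round(cnt$count))
  cnt[cnt$count > 0L, , drop = FALSE]
}

#' Cohort-wide allele support and the resolvable allele sets
#'
#' An allele is resolvable when its unique-mapper count summed over the
#' whole cohort reaches `min_support`. Per region, the unresolvable
#' remainder is collapsed: its single most abundant allele (by atlas
#' abundance, ties broken by allele id) is retained as a representative and
#' the rest are dropped.
#'
#' @param u data frame of per-participant unique counts with columns
#'   `participant_id`, `region_id`, `allele_id`, `count`.
#' @param atlas an [rdna_atlas()] (supplies the full allele set and atlas
#'   abundances).
#' @param min_support cohort unique-mapper threshold (default 2, "at least
#'   2" semantics).
#' @param strict use a strict `>` comparison instead of `>=`.
#' @return named list per region: `resolved` (the supported alleles),
#'   `retained` (the representative of the collapsed set, or NULL),
#'   `resolvable` (their union), `zero_support` flag. Class `allele_support`.
#' @export
cohort_allele_support <- function(u, atlas, min_support = 2L,
                                  strict = FALSE) {
  stopifnot(inherits(atlas, "rdna_atlas"))
  sums <- stats::aggregate(count ~ region_id + allele_id, data = u, FUN = sum)
  out <- list()
  for (rid in atlas$regions$region_id) {
    al <- atlas$alleles[atlas$alleles$region_id == rid, , drop = FALSE]
    if (nrow(al) == 0L) next
    s <- sums[sums$region_id == rid, , drop = FALSE]
    support <- stats::setNames(rep(0, nrow(al)), al$allele_id)
    support[s$allele_id] <- s$count
    keep <- if (strict) support > min_support else support >= min_support
    resolved <- al$allele_id[keep[al$allele_id]]
    excluded <- setdiff(al$allele_id, resolved)
    retained <- NULL
    if (length(excluded)) {
      ex <- al[al$allele_id %in% excluded, , drop = FALSE]
      ex <- ex[order(-ex$atlas_abundance, ex$allele_id), , drop = FALSE]
      retained <- ex$allele_id[1L]
    }
    out[[rid]] <- list(resolved = resolved, retained = retained,
                       resolvable = c(resolved, retained),
                       zero_support = sum(support) == 0)
  }
  structure(out, class = "allele_support")
}

#' Recount unique mappers over the collapsed allele sets
#'
#' After collapsing, a read counts as unique when (a) it hits exactly one
#' resolved allele and nothing else, or (b) all its hits fall on excluded
#' (indistinguishable) alleles of a single region, in which case it is
#' credited to that region's retained representative. Reads hitting both a
#' resolved allele and excluded alleles stay multi-mappers (conservative).
#'
#' @param hits hits data frame for one participant.
#' @param support an `allele_support` from [cohort_allele_support()].
#' @return data frame `region_id`, `allele_id`, `count` over the
#'   resolvable allele sets.
#' @export
recount_with_collapsed_alleles <- function(hits, support) {
  if (nrow(hits) == 0L)
    return(data.frame(region_id = character(), allele_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  u <- unique(hits[c("read_id", "region_id", "allele_id")])
  resolved_of <- lapply(support, `[[`, "resolved")
  u$in_resolved <- mapply(function(r, a) a %in% resolved_of[[r]],
                          u$region_id, u$allele_id)
  per_read <- split(u, u$read_id)
  recs <- lapply(per_read, function(h) {
    n_res <- sum(h$in_resolved)
    if (n_res == 1L && nrow(h) == 1L) {
      h[1L, c("region_id", "allele_id")]
    } else if (n_res == 0L && length(unique(h$region_id)) == 1L) {
      rid <- h$region_id[1L]
      rep_al <- support[[rid]]$retained
      if (is.null(rep_al)) return(NULL)
      data.frame(region_id = rid, allele_id = rep_al,
                 stringsAsFactors = FALSE)
    } else NULL
  })
  recs <- do.call(rbind, recs[!vapply(recs, is.null, TRUE)])
  if (is.null(recs))
    return(data.frame(region_id = character(), allele_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(list(count = rep(1L, nrow(recs))),
                          by = recs[c("region_id", "allele_id")], FUN = sum)
  agg <- agg[order(agg$region_id, agg$allele_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Segment read depth and cohort depth QC
#'
#' Default depth is per-base coverage, `d = sum(u+) * read_length / L_s`;
#' `mode = "literal"` uses the plain count-over-length ratio `sum(u+)/L_s`.
#' A region passes QC when its cohort median depth is at least `min_median`.
#'
#' @param u_plus data frame with `participant_id`, `region_id`,
#'   `allele_id`, `count` (collapsed unique counts, cohort-wide).
#' @param regions the atlas regions data frame (for segment lengths).
#' @param read_length read length in bases (default 150).
#' @param mode `"coverage"` (default) or `"literal"`.
#' @param min_median cohort-median depth threshold (default 30).
#' @return list with `per_participant` (data frame `participant_id`,
#'   `region_id`, `depth`) and `per_region` (data frame `region_id`,
#'   `median_depth`, `pass_qc`).
#' @export
segment_depth <- function(u_plus, regions, read_length = 150L,
                          mode = c("coverage", "literal"), min_median = 30) {
  mode <- match.arg(mode)
  participants <- unique(u_plus$participant_id)
  tot <- stats::aggregate(count ~ participant_id + region_id,
                          data = u_plus, FUN = sum)
  grid <- expand.grid(participant_id = participants,
                      region_id = regions$region_id,
                      stringsAsFactors = FALSE)
  m <- merge(grid, tot, all.x = TRUE)
  m$count[is.na(m$count)] <- 0
  L <- stats::setNames(regions$length, regions$region_id)
  mult <- if (mode == "coverage") as.numeric(read_length) else 1
  m$depth <- m$count * mult / L[m$region_id]
  med <- stats::aggregate(depth ~ region_id, data = m, FUN = stats::median)
  names(med)[2L] <- "median_depth"
  med$pass_qc <- med$median_depth >= min_median
  list(per_participant = m[order(m$participant_id, m$region_id),
                           c("participant_id", "region_id", "depth")],
       per_region = med)
}

#' Resolve allele frequencies and the burden statistic for one participant
#'
#' For each region: allele frequencies `pi = u+/sum(u+)` over the
#' resolvable set; per-allele copy numbers `c = pi * c45S`; copies below
#' `zero_threshold` (default 1) are zeroed as likely somatic low-frequency
#' clones; frequencies are renormalized to `pi_star = c_star/sum(c_star)`;
#' MAF is the largest `pi_star` and burden is `1 - MAF`.
#'
#' @param u_plus_p collapsed counts for one participant (`region_id`,
#'   `allele_id`, `count`).
#' @param c45S the participant's estimated 45S copy number.
#' @param support an `allele_support` (defines the resolvable sets).
#' @param zero_threshold copy-number floor below which alleles are zeroed.
#' @return data frame per (region, allele): `region_id`, `allele_id`, `pi`,
#'   `copy`, `copy_star`, `pi_star`, plus per-region `maf`, `burden` and an
#'   `unresolved` flag (all copies zeroed).
#' @export
resolve_frequencies <- function(u_plus_p, c45S, support, zero_threshold = 1) {
  if (c45S < 0) stop("c45S must be non-negative")
  out <- list()
  for (rid in names(support)) {
    alleles <- support[[rid]]$resolvable
    if (length(alleles) == 0L) next
    sub <- u_plus_p[u_plus_p$region_id == rid, , drop = FALSE]
    counts <- stats::setNames(rep(0, length(alleles)), alleles)
    counts[sub$allele_id[sub$allele_id %in% alleles]] <-
      sub$count[sub$allele_id %in% alleles]
    total <- sum(counts)
    if (total <= 0) next                       # missing (participant, region)
    pi <- counts / total
    copy <- pi * c45S
    copy_star <- ifelse(copy < zero_threshold, 0, copy)
    unresolved <- sum(copy_star) <= 0
    pi_star <- if (unresolved) rep(NA_real_, length(copy_star)) else
      copy_star / sum(copy_star)
    maf <- if (unresolved) NA_real_ else max(pi_star)
    out[[rid]] <- data.frame(
      region_id = rid, allele_id = alleles, pi = unname(pi),
      copy = unname(copy), copy_star = unname(copy_star),
      pi_star = unname(pi_star), maf = maf, burden = 1 - maf,
      unresolved = unresolved, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(region_id = character(), allele_id = character(),
                      pi = numeric(), copy = numeric(),
                      copy_star = numeric(), pi_star = numeric(),
                      maf = numeric(), burden = numeric(),
                      unresolved = logical(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Cohort burden / MAF matrices
#'
#' @param results named list of [resolve_frequencies()] outputs, one per
#'   participant.
#' @param depth_qc `per_region` QC table from [segment_depth()]; regions
#'   failing the cohort-median depth filter become NA for everyone.
#' @param regions the atlas regions data frame (for ES/non-ES annotation).
#' @return list with matrices `burden` and `maf` (participants x regions,
#'   NA where QC failed or unresolved) and the per-region class annotation.
#' @export
region_burden_table <- function(results, depth_qc = NULL, regions = NULL) {
  participants <- names(results)
  rids <- unique(unlist(lapply(results, function(r) r$region_id)))
  if (!is.null(regions))
    rids <- intersect(regions$region_id, union(rids, regions$region_id))
  burden <- maf <- matrix(NA_real_, length(participants), length(rids),
                          dimnames = list(participants, rids))
  for (p in participants) {
    r <- results[[p]]
    per_region <- unique(r[c("region_id", "maf", "burden", "unresolved")])
    ok <- !per_region$unresolved
    burden[p, per_region$region_id[ok]] <- per_region$burden[ok]
    maf[p, per_region$region_id[ok]] <- per_region$maf[ok]
  }
  if (!is.null(depth_qc)) {
    fail <- depth_qc$region_id[!depth_qc$pass_qc]
    fail <- intersect(fail, colnames(burden))
    burden[, fail] <- NA_real_
    maf[, fail] <- NA_real_
  }
  cls <- if (!is.null(regions))
    stats::setNames(regions$region_class, regions$region_id)[rids] else NULL
  list(burden = burden, maf = maf, region_class = cls)
}

#' Full burden pipeline for a cohort of hit sets
#'
#' Convenience wrapper chaining [unique_mapper_counts()],
#' [cohort_allele_support()], [recount_with_collapsed_alleles()],
#' [segment_depth()], [resolve_frequencies()] and [region_burden_table()].
#'
#' @param hits_by_participant named list of hits data frames.
#' @param atlas an [rdna_atlas()].
#' @param c45S named numeric vector of per-participant 45S copy numbers.
#' @param min_support,strict passed to [cohort_allele_support()].
#' @param read_length,depth_mode,min_median passed to [segment_depth()].
#' @param zero_threshold passed to [resolve_frequencies()].
#' @return list: `support`, `u`, `u_plus`, `depth`, `results`, `tables`
#'   (the burden/maf matrices).
#' @export
rdna_burden <- function(hits_by_participant, atlas, c45S,
                        min_support = 2L, strict = FALSE,
                        read_length = 150L,
                        depth_mode = c("coverage", "literal"),
                        min_median = 30, zero_threshold = 1) {
  depth_mode <- match.arg(depth_mode)
  participants <- names(hits_by_participant)
  stopifnot(!is.null(participants), all(participants %in% names(c45S)))
  u_list <- lapply(hits_by_participant, unique_mapper_counts)
  u <- do.call(rbind, lapply(participants, function(p) {
    if (nrow(u_list[[p]]) == 0L) return(NULL)
    cbind(participant_id = p, u_list[[p]])
  }))
  if (is.null(u)) stop("no unique mappers anywhere in the cohort")
  support <- cohort_allele_support(u, atlas, min_support = min_support,
                                   strict = strict)
  up_list <- lapply(hits_by_participant, recount_with_collapsed_alleles,
                    support = support)
  u_plus <- do.call(rbind, lapply(participants, function(p) {
    if (nrow(up_list[[p]]) == 0L) return(NULL)
    cbind(participant_id = p, up_list[[p]])
  }))
  depth <- segment_depth(u_plus, atlas$regions, read_length = read_length,
                         mode = depth_mode, min_median = min_median)
  results <- lapply(participants, function(p)
    resolve_frequencies(up_list[[p]], c45S[[p]], support,
                        zero_threshold = zero_threshold))
  names(results) <- participants
  tables <- region_burden_table(results, depth_qc = depth$per_region,
                                regions = atlas$regions)
  list(support = support, u = u, u_plus = u_plus, depth = depth,
       results = results, tables = tables)
}

#' Write the cohort burden table as TSV
#' @param pipeline output of [rdna_burden()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_burden_tsv <- function(pipeline, path) {
  b <- pipeline$tables$burden; m <- pipeline$tables$maf
  dd <- pipeline$depth$per_participant
  qc <- stats::setNames(pipeline$depth$per_region$pass_qc,
                        pipeline$depth$per_region$region_id)
  rows <- do.call(rbind, lapply(rownames(b), function(p) {
    data.frame(participant_id = p, region_id = colnames(b),
               maf = m[p, ], burden = b[p, ],
               depth = dd$depth[dd$participant_id == p][
                 match(colnames(b), dd$region_id[dd$participant_id == p])],
               pass_depth_qc = unname(qc[colnames(b)]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  write_tsv_commented(rows, path,
    "burden = 1 - major allele frequency; NA = failed QC or unresolved")
}
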