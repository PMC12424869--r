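# Synthetic rDNA cohorts: atlas generation, multi-copy participant genomes
# with twin-shared germline haplotypes and per-copy somatic injections,
# GC-aware 150 b reads with two-state qualities, a count-level sampling
# shortcut, and phenotypes driven by variant frequencies. Everything is
# seeded: identical configs give byte-identical artifacts.

#' Simulation configuration with study-scale defaults
#'
#' Defaults encode the structure the pipeline targets: hundreds of 45S
#' copies per genome (mean 400), 150 b reads, a high/low (Q37/Q10) base
#' quality mixture, and regions tiling two subunits alternating ES and
#' non-ES. Rates are probabilities in `[0, 1]`.
#'
#' @param seed mandatory RNG seed.
#' @param ... overrides of the default fields (see the returned list).
#' @return named list of class `sim_config`.
#' @export
sim_config <- function(seed, ...) {
  cfg <- list(
    seed = as.integer(seed),
    subunit_lengths = c("18S" = 1200L, "28S" = 2400L),
    regions_per_subunit = c("18S" = 2L, "28S" = 4L),
    alleles_per_region = 4L,
    germline_alleles_per_region = NULL,  # default: all alleles germline
    variant_pool_size = 5L,       # candidate variants per region
    indel_prob = 0.15,            # chance a pool variant is an indel
    gc_rich_tracts = FALSE,
    germline_concentration = 20,  # Dirichlet concentration on atlas abundances
    n_participants = 20L,
    n_twin_pairs = 5L,
    somatic_rate = 0.002,         # per-copy injection probability
    copy_number_mean = 400,
    copy_number_sd = 80,
    cn_somatic_coupling = 0,      # >0 couples somatic load to CN expansion
    read_length = 150L,
    depth = 2000L,                # reads per region per participant
    error_rate = 0,
    low_quality_rate = 0.02,
    q_high = 37L, q_low = 10L,
    gc_bias_strength = 0,
    flank_len = 150L,
    n_batches = 3L,
    n_pcs = 20L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  if (cfg$alleles_per_region < 1L) stop("alleles_per_region must be >= 1")
  if (is.null(cfg$germline_alleles_per_region))
    cfg$germline_alleles_per_region <- cfg$alleles_per_region
  if (cfg$germline_alleles_per_region < 1L ||
      cfg$germline_alleles_per_region > cfg$alleles_per_region)
    stop("germline_alleles_per_region must be in [1, alleles_per_region]")
  if (2L * cfg$n_twin_pairs > cfg$n_participants)
    stop("n_twin_pairs x 2 exceeds n_participants")
  rates <- c(cfg$indel_prob, cfg$somatic_rate, cfg$error_rate,
             cfg$low_quality_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  structure(cfg, class = c("sim_config", "list"))
}

random_dna <- function(n, gc_tracts = FALSE) {
  s <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (gc_tracts && n > 60L) {
    for (at in seq(20L, n - 12L, by = 120L)) {
      tract <- strsplit(strrep(sample(c("GGGGCC", "GCGGGC"), 1L), 2L), "")[[1L]]
      s[at:(at + length(tract) - 1L)] <- tract
    }
  }
  paste(s, collapse = "")
}

other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Simulate a variant atlas
#'
#' Generates subunit references, a region tiling alternating ES/non-ES,
#' and per region a reference allele plus variant-carrying alleles built
#' from a pool of SNVs and left-anchored indels. Atlas abundances follow a
#' decreasing spectrum with the reference allele most abundant.
#'
#' @param config a [sim_config()].
#' @return an [rdna_atlas()] whose alleles carry explicit variant lists.
#' @export
simulate_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  reference <- vapply(config$subunit_lengths, random_dna, "",
                      gc_tracts = config$gc_rich_tracts)
  names(reference) <- names(config$subunit_lengths)
  regions <- do.call(rbind, lapply(names(reference), function(su) {
    n <- config$regions_per_subunit[[su]]
    L <- nchar(reference[[su]])
    bounds <- floor(seq(0L, L, length.out = n + 1L))
    data.frame(region_id = sprintf("%s_r%02d", tolower(su), seq_len(n)),
               subunit_id = su,
               region_class = rep_len(c("ES", "non-ES"), n),
               start = bounds[-(n + 1L)] + 1L, end = bounds[-1L],
               stringsAsFactors = FALSE)
  }))
  alleles <- list()
  for (i in seq_len(nrow(regions))) {
    reg <- regions[i, ]
    refseq <- substr(reference[[reg$subunit_id]], reg$start, reg$end)
    # candidate variant pool: positions spaced >= 8 bp, away from edges
    margin <- 6L
    L <- nchar(refseq)
    pool_n <- config$variant_pool_size
    pos_grid <- seq(margin, L - margin, length.out = pool_n + 2L)
    pos <- sort(sample(round(pos_grid[2:(pool_n + 1L)]) +
                         sample(-2:2, pool_n, replace = TRUE)))
    pool <- vapply(pos, function(p) {
      refb <- substr(refseq, p, p)
      if (runif(1) < config$indel_prob) {
        if (runif(1) < 0.5) {              # insertion after p
          ins <- paste(sample(c("A", "C", "G", "T"),
                              sample(1:3, 1L), replace = TRUE),
                       collapse = "")
          format_variant_key(reg$start - 1L + p, refb, paste0(refb, ins))
        } else {                           # deletion of 1-3 bases after p
          dl <- sample(1:3, 1L)
          span <- substr(refseq, p, min(p + dl, L - 2L))
          format_variant_key(reg$start - 1L + p, span, refb)
        }
      } else {
        format_variant_key(reg$start - 1L + p, refb, other_base(refb))
      }
    }, "")
    # left-normalize pool keys so declared sets match alignment-derived ones
    pool <- vapply(pool, function(kk) {
      core <- apply_variant_keys(refseq, reg$start, kk)
      ks <- derive_variant_keys(core, refseq, reg$start)
      if (length(ks) == 1L) ks else kk
    }, "", USE.NAMES = FALSE)
    pool <- unique(pool)
    sets <- list(character())             # reference allele first
    guard <- 0L
    while (length(sets) < config$alleles_per_region && guard < 200L) {
      guard <- guard + 1L
      cand <- sort(sample(pool, sample(seq_len(min(3L, length(pool))), 1L)))
      cand_pos <- parse_variant_key(cand)
      ends <- cand_pos$position + nchar(cand_pos$ref) - 1L
      if (nrow(cand_pos) > 1L &&
          any(cand_pos$position[-1L] <= ends[-nrow(cand_pos)] + 1L)) next
      if (any(vapply(sets, identical, TRUE, y = cand))) next
      sets[[length(sets) + 1L]] <- cand
    }
    ab <- sort(rgamma(length(sets), shape = 1), decreasing = TRUE)
    ab <- ab / sum(ab)
    ab <- c(max(ab), sort(ab[-which.max(ab)], decreasing = TRUE))
    alleles[[i]] <- data.frame(
      region_id = reg$region_id,
      allele_id = sprintf("a%02d", seq_along(sets)),
      core_sequence = vapply(sets, function(ks)
        apply_variant_keys(refseq, reg$start, ks), ""),
      atlas_abundance = ab, stringsAsFactors = FALSE)
    alleles[[i]]$variants <- sets
  }
  rdna_atlas(reference, regions, do.call(rbind, alleles),
             flank_len = config$flank_len)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) g <- rep(1, length(alpha))
  g / sum(g)
}

#' Simulate a cohort of multi-copy rDNA genomes
#'
#' Twin pairs (the first `2 * n_twin_pairs` participants) share a germline
#' haplotype: identical per-region allele copy compositions and copy
#' number. Somatic variation is injected per participant as per-copy
#' conversions of major-allele copies into low-abundance atlas alleles at
#' `somatic_rate`, optionally coupled to copy-number expansion via
#' `cn_somatic_coupling`.
#'
#' @param atlas an [rdna_atlas()] (typically from [simulate_atlas()]).
#' @param config a [sim_config()].
#' @return list of class `cohort_truth`: `participants` (covariates +
#'   `c45S_true` + `haplotype_id`), `copies` (participant x region x allele
#'   copy counts, long), `true_freq` and `germline_freq` (participants x
#'   variant-key matrices), `twin_pairs`, `lookup`.
#' @export
simulate_cohort <- function(atlas, config) {
  stopifnot(inherits(atlas, "rdna_atlas"), inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  lookup <- build_lookup_table(atlas)
  n <- config$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  twin_pairs <- if (config$n_twin_pairs > 0L)
    data.frame(id_a = ids[2L * seq_len(config$n_twin_pairs) - 1L],
               id_b = ids[2L * seq_len(config$n_twin_pairs)],
               stringsAsFactors = FALSE) else
    data.frame(id_a = character(), id_b = character())
  hap_of <- seq_len(n)
  if (config$n_twin_pairs > 0L)
    hap_of[2L * seq_len(config$n_twin_pairs)] <-
      hap_of[2L * seq_len(config$n_twin_pairs) - 1L]
  haplos <- unique(hap_of)
  # per-haplotype germline: copy number + per-region copy composition
  cn_h <- stats::setNames(pmax(50, round(rnorm(length(haplos),
    config$copy_number_mean, config$copy_number_sd))), haplos)
  region_ids <- atlas$regions$region_id
  germ <- list()
  for (h in haplos) {
    for (rid in region_ids) {
      al <- atlas$alleles[atlas$alleles$region_id == rid, ]
      g <- min(config$germline_alleles_per_region, nrow(al))
      prop <- rdirichlet1(config$germline_concentration *
                            al$atlas_abundance[seq_len(g)] + 1e-3)
      copies <- rep(0L, nrow(al))
      copies[seq_len(g)] <- as.vector(
        rmultinom(1L, cn_h[[as.character(h)]], prop))
      germ[[paste(h, rid)]] <- data.frame(
        haplotype = h, region_id = rid, allele_id = al$allele_id,
        copies = copies, stringsAsFactors = FALSE)
    }
  }
  # per-participant somatic injection on top of the shared germline
  copies_rows <- list()
  for (i in seq_len(n)) {
    h <- hap_of[i]
    cn <- cn_h[[as.character(h)]]
    coupling <- (cn / config$copy_number_mean)^config$cn_somatic_coupling
    for (rid in region_ids) {
      g <- germ[[paste(h, rid)]]
      copies <- stats::setNames(g$copies, g$allele_id)
      al <- atlas$alleles[atlas$alleles$region_id == rid, ]
      g <- min(config$germline_alleles_per_region, nrow(al))
      low <- if (g < nrow(al)) al$allele_id[-seq_len(g)] else
        al$allele_id[al$atlas_abundance <= stats::median(al$atlas_abundance)]
      low <- setdiff(low, names(which.max(copies)))
      n_inject <- rbinom(1L, cn, min(1, config$somatic_rate * coupling))
      if (length(low) && n_inject > 0L) {
        for (tgt in sample(low, n_inject, replace = TRUE)) {
          donor <- names(which.max(copies))
          if (copies[donor] > 1L && donor != tgt) {
            copies[donor] <- copies[donor] - 1L
            copies[tgt] <- copies[tgt] + 1L
          }
        }
      }
      copies_rows[[length(copies_rows) + 1L]] <- data.frame(
        participant_id = ids[i], region_id = rid,
        allele_id = names(copies), copies = unname(copies),
        stringsAsFactors = FALSE)
    }
  }
  copies <- do.call(rbind, copies_rows)
  freq_from_copies <- function(cp) {
    cl <- split(cp[c("region_id", "allele_id", "copies")],
                cp$participant_id)
    cl <- lapply(cl, function(d) {
      names(d)[3L] <- "count"; d
    })
    variant_frequency_table(cl, lookup)$freq
  }
  true_freq <- freq_from_copies(copies)[ids, , drop = FALSE]
  germ_copies <- do.call(rbind, lapply(seq_len(n), function(i) {
    do.call(rbind, lapply(region_ids, function(rid) {
      g <- germ[[paste(hap_of[i], rid)]]
      data.frame(participant_id = ids[i], region_id = rid,
                 allele_id = g$allele_id, copies = g$copies,
                 stringsAsFactors = FALSE)
    }))
  }))
  germline_freq <- freq_from_copies(germ_copies)[ids, , drop = FALSE]
  age <- round(runif(length(haplos), 40, 70))
  sex <- rbinom(length(haplos), 1L, 0.5)
  participants <- data.frame(
    participant_id = ids, haplotype_id = hap_of,
    c45S_true = unname(cn_h[as.character(hap_of)]),
    age = age[match(hap_of, haplos)], sex = sex[match(hap_of, haplos)],
    batch = sample(sprintf("B%d", seq_len(config$n_batches)), n,
                   replace = TRUE),
    rdna_cn = unname(cn_h[as.character(hap_of)]),
    stringsAsFactors = FALSE)
  pcs <- matrix(rnorm(n * config$n_pcs), n,
                dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
  participants <- cbind(participants, pcs)
  participants$birth_year <- 2020L - participants$age
  structure(list(participants = participants, copies = copies,
                 true_freq = true_freq, germline_freq = germline_freq,
                 twin_pairs = twin_pairs, lookup = lookup),
            class = "cohort_truth")
}

#' Simulate kinship records for a cohort
#'
#' Twin pairs get kinship near 0.5 (sd 0.02); a set of random unrelated
#' pairs gets kinship near 0. Birth years come from the cohort covariates.
#'
#' @param truth a `cohort_truth` from [simulate_cohort()].
#' @param n_unrelated_pairs number of noise pairs to add.
#' @param seed RNG seed.
#' @return kinship data frame (`id_a`, `id_b`, `kinship`, `birth_year_a`,
#'   `birth_year_b`).
#' @export
simulate_kinship <- function(truth, n_unrelated_pairs = 20L, seed = 1L) {
  set.seed(seed)
  ids <- truth$participants$participant_id
  by <- stats::setNames(truth$participants$birth_year, ids)
  tw <- truth$twin_pairs
  rows <- if (nrow(tw))
    data.frame(id_a = tw$id_a, id_b = tw$id_b,
               kinship = pmin(0.52, rnorm(nrow(tw), 0.5, 0.02)),
               stringsAsFactors = FALSE) else NULL
  if (n_unrelated_pairs > 0L && length(ids) >= 2L) {
    pick <- replicate(n_unrelated_pairs, sample(ids, 2L))
    rows <- rbind(rows, data.frame(
      id_a = pick[1L, ], id_b = pick[2L, ],
      kinship = pmax(0, rnorm(n_unrelated_pairs, 0.02, 0.01)),
      stringsAsFactors = FALSE))
  }
  rows$birth_year_a <- unname(by[rows$id_a])
  rows$birth_year_b <- unname(by[rows$id_b])
  rows
}

gc_window_weights <- function(seq, read_length, strength) {
  n <- nchar(seq)
  O <- n - read_length + 1L
  if (O < 1L) return(numeric())
  if (strength == 0) return(rep(1, O))
  isgc <- as.integer(strsplit(seq, "")[[1L]] %in% c("G", "C"))
  cs <- c(0L, cumsum(isgc))
  gc <- (cs[(read_length + 1L):(n + 1L)] - cs[1L:O]) / read_length
  # logistic down-weighting of high-GC windows
  stats::plogis(-strength * 10 * (gc - 0.5))
}

#' Simulate short reads for a cohort
#'
#' Reads are drawn per region at the configured depth, from alleles in
#' proportion to the participant's copy composition, at start positions
#' uniform over the extended allele (down-weighted in high-GC windows by a
#' logistic function when `gc_bias_strength > 0`), on a random strand.
#' Sequencing errors are substitutions at `error_rate` and always carry
#' low base quality; a further `low_quality_rate` of error-free bases also
#' get low quality, giving the two-state Q37/Q10 mixture.
#'
#' @param truth a `cohort_truth`.
#' @param atlas the atlas the cohort was simulated from.
#' @param config the [sim_config()].
#' @param participants subset of participant ids (default: all).
#' @return named list of read data frames (`read_id`, `sequence`,
#'   `quality`), each with a `provenance` attribute recording the true
#'   (region, allele, offset, strand) of every read.
#' @export
simulate_reads <- function(truth, atlas, config, participants = NULL) {
  stopifnot(inherits(truth, "cohort_truth"), inherits(config, "sim_config"))
  if (config$depth <= 0L) stop("depth must be positive")
  set.seed(config$seed + 2L)
  if (is.null(participants))
    participants <- truth$participants$participant_id
  rl <- config$read_length
  ext <- stats::setNames(atlas$alleles$extended_sequence,
                         paste(atlas$alleles$region_id,
                               atlas$alleles$allele_id, sep = "|"))
  wts <- lapply(ext, gc_window_weights, read_length = rl,
                strength = config$gc_bias_strength)
  bases <- c("A", "C", "G", "T")
  out <- list()
  for (p in participants) {
    cp <- truth$copies[truth$copies$participant_id == p, ]
    recs <- list(); prov <- list(); serial <- 0L
    for (rid in unique(cp$region_id)) {
      sub <- cp[cp$region_id == rid & cp$copies > 0L, ]
      if (nrow(sub) == 0L) next
      draw <- as.vector(rmultinom(1L, config$depth,
                                  sub$copies / sum(sub$copies)))
      for (k in seq_len(nrow(sub))) {
        if (draw[k] == 0L) next
        id <- paste(rid, sub$allele_id[k], sep = "|")
        w <- wts[[id]]
        # allele shorter than the read: one full-length window
        rl_i <- min(rl, nchar(ext[[id]]))
        if (length(w) == 0L) w <- 1
        offs <- sample.int(length(w), draw[k], replace = TRUE, prob = w) - 1L
        strands <- sample(c("+", "-"), draw[k], replace = TRUE)
        for (m in seq_len(draw[k])) {
          serial <- serial + 1L
          sq <- substr(ext[[id]], offs[m] + 1L, offs[m] + rl_i)
          ch <- strsplit(sq, "")[[1L]]
          err <- runif(rl_i) < config$error_rate
          if (any(err))
            ch[err] <- vapply(ch[err], other_base, "")
          lowq <- err | (runif(rl_i) < config$low_quality_rate)
          q <- ifelse(lowq, config$q_low, config$q_high)
          sq <- paste(ch, collapse = "")
          if (strands[m] == "-") {
            sq <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(sq)))
            q <- rev(q)
          }
          recs[[serial]] <- data.frame(
            read_id = sprintf("%s_%06d", p, serial), sequence = sq,
            quality = int_to_phred(q), stringsAsFactors = FALSE)
          prov[[serial]] <- data.frame(
            read_id = sprintf("%s_%06d", p, serial), region_id = rid,
            allele_id = sub$allele_id[k], offset = offs[m],
            strand = strands[m], stringsAsFactors = FALSE)
        }
      }
    }
    reads <- do.call(rbind, recs)
    attr(reads, "provenance") <- do.call(rbind, prov)
    out[[p]] <- reads
  }
  out
}

#' Count-level sampling of a cohort variant-frequency table
#'
#' Samples per-region allele read counts directly from each participant's
#' copy composition (multinomial at the given depth) and converts them via
#' the lookup table — the read-count sampling noise of error-free,
#' uniquely-assigned reads without simulating sequences. Used for
#' cohort-scale heritability and association studies where per-base
#' simulation adds nothing.
#'
#' @param truth a `cohort_truth`.
#' @param depth reads per region.
#' @param seed RNG seed.
#' @return a [variant_frequency_table()].
#' @export
simulate_frequency_table <- function(truth, depth = 5000L, seed = 1L) {
  set.seed(seed)
  counts <- lapply(split(truth$copies, truth$copies$participant_id),
                   function(cp) {
    do.call(rbind, lapply(split(cp, cp$region_id), function(d) {
      data.frame(region_id = d$region_id, allele_id = d$allele_id,
                 count = as.vector(rmultinom(1L, depth,
                                             d$copies / sum(d$copies))),
                 stringsAsFactors = FALSE)
    }))
  })
  ids <- truth$participants$participant_id
  vft <- variant_frequency_table(counts[ids], truth$lookup)
  vft
}

#' Simulate phenotypes driven by variant frequencies and region burden
#'
#' Quantitative traits are linear in the true variant frequencies plus
#' small age/sex effects and Gaussian noise; disease indicators follow a
#' logistic model on region burden with an intercept solved for the target
#' prevalence.
#'
#' @param truth a `cohort_truth`.
#' @param effects named numeric vector: variant key -> linear effect.
#' @param noise_sd Gaussian noise sd (default 1).
#' @param disease_spec named numeric vector: region id -> log-odds per
#'   burden unit (optional).
#' @param burden matrix participants x regions (needed with
#'   `disease_spec`).
#' @param prevalence target disease prevalence (default 0.1).
#' @param age_beta,sex_beta covariate effects on the trait.
#' @param trait_name,disease_name output column names.
#' @param seed RNG seed.
#' @return list `traits` (data frame participant_id + trait columns) and
#'   `cases` (participant_id + 0/1 indicator columns; NULL without
#'   `disease_spec`).
#' @export
simulate_phenotypes <- function(truth, effects = numeric(), noise_sd = 1,
                                disease_spec = NULL, burden = NULL,
                                prevalence = 0.1, age_beta = 0.01,
                                sex_beta = 0.2, trait_name = "trait1",
                                disease_name = "D1", seed = 1L) {
  set.seed(seed)
  ids <- truth$participants$participant_id
  unknown <- setdiff(names(effects), colnames(truth$true_freq))
  if (length(unknown))
    stop("unknown variant key(s) in effect spec: ",
         paste(unknown, collapse = ", "))
  lin <- rep(0, length(ids))
  for (kk in names(effects)) {
    f <- truth$true_freq[ids, kk]
    f[is.na(f)] <- 0
    lin <- lin + effects[[kk]] * f
  }
  y <- lin + age_beta * truth$participants$age +
    sex_beta * truth$participants$sex + rnorm(length(ids), 0, noise_sd)
  traits <- data.frame(participant_id = ids, y, stringsAsFactors = FALSE)
  names(traits)[2L] <- trait_name
  cases <- NULL
  if (!is.null(disease_spec)) {
    if (is.null(burden)) stop("disease_spec needs a burden matrix")
    eta <- rep(0, length(ids))
    for (rid in names(disease_spec)) {
      b <- burden[ids, rid]
      b[is.na(b)] <- 0
      eta <- eta + disease_spec[[rid]] * b
    }
    intercept <- stats::qlogis(prevalence) - mean(eta)
    pr <- stats::plogis(intercept + eta)
    cases <- data.frame(participant_id = ids,
                        d = rbinom(length(ids), 1L, pr),
                        stringsAsFactors = FALSE)
    names(cases)[2L] <- disease_name
  }
  list(traits = traits, cases = cases)
}
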