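# Synthetic-cohort generator. Emulates the statistical structure of a
# TCL1-transgenic CLL mouse cohort at the clone-table level: clone-fraction
# hierarchies (mono/bi/oligoclonal), a polyclonal wild-type background,
# IGHV subgroup structure with stereotyped CDR3s for IGHV11/IGHV12 and
# diverse N-insertion-rich CDR3s for IGHV1, sex-linked subgroup assignment,
# per-stratum survival laws, longitudinal repertoires with a growing
# dominant clone, and paired spleen / lymph-node repertoires with
# occasional dominant-clone switching and subgroup-dependent LN sizes.

#' Cohort specification for the synthetic generator
#'
#' All defaults encode the study conditions the generator emulates:
#' cohort sizes (85 TCL1, 8 WT), the clonality mixture (47/31/22%
#' mono/bi/oligoclonal), the IGHV subgroup mixture (27/49/12% for
#' IGHV1/IGHV11/IGHV12, remainder "other"), sex linkage (73% of IGHV1 and
#' 43% of IGHV11 dominant clones in females), junction-insertion models
#' (IGHV1: negative binomial with median 4 and IQR 2-5; IGHV11/IGHV12:
#' point mass at 0 with a 10% geometric tail), invariant stereotyped CDR3s
#' for IGHV11/IGHV12, per-stratum log-normal survival medians (IGHV1 322 d,
#' IGHV11 371 d, IGHV12 334 d; sex-specific 308/344/378/364 d; marginal
#' male 355 d, female 337 d), a wild-type background law calibrated so
#' top-10 clone fractions fall in roughly 1-4% with median near 1.5%, a
#' logistic longitudinal growth law, a 4/9 probability that an
#' IGHV11-dominant spleen pairs with an IGHV1-dominant lymph node, and
#' log-normal LN sizes with medians 4.5 mm (IGHV1) and 2.6 mm (IGHV11).
#'
#' @param n_tcl1,n_wt Cohort sizes.
#' @param clonality_mix Named probabilities for `mono`, `bi`, `oligo`.
#' @param subgroup_mix Named probabilities over `IGHV1`, `IGHV11`,
#'   `IGHV12`, `other`.
#' @param p_female Named P(female | dominant subgroup).
#' @param p_dominant Probability that a mouse's top clone reaches the
#'   dominance threshold (61 of 85 mice in the emulated design).
#' @param survival_sdlog Log-scale SD of the survival law.
#' @param total_reads Reads per simulated sample.
#' @param n_longitudinal Mice (per genotype) followed by monthly blood
#'   draws.
#' @param n_ln_pairs Mice with a paired lymph-node repertoire.
#' @param ... Overrides for the remaining calibrated laws (see the
#'   returned object for field names).
#' @return An object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_tcl1 = 85, n_wt = 8,
                        clonality_mix = c(mono = 0.47, bi = 0.31,
                                          oligo = 0.22),
                        subgroup_mix = c(IGHV1 = 0.27, IGHV11 = 0.49,
                                         IGHV12 = 0.12, other = 0.12),
                        p_female = c(IGHV1 = 0.73, IGHV11 = 0.43,
                                     IGHV12 = 0.48, other = 0.48),
                        p_dominant = 0.72,
                        survival_sdlog = 0.15,
                        total_reads = 30000,
                        n_longitudinal = 14,
                        n_ln_pairs = 18,
                        ...) {
  spec <- list(
    n_tcl1 = n_tcl1, n_wt = n_wt,
    clonality_mix = clonality_mix,
    subgroup_mix = subgroup_mix,
    p_female = p_female,
    p_dominant = p_dominant,
    # dominant fraction: 0.5 + (cap - 0.5) * Beta(2, 3)
    dominant_beta = c(2, 3),
    # insertion models, solved so distribution quartiles are (2, 4, 5)
    insertion_model = list(
      IGHV1 = list(type = "nbinom", size = 21, mu = 4.1),
      IGHV11 = list(type = "zero_tail", p_zero = 0.9, geom_prob = 0.5),
      IGHV12 = list(type = "zero_tail", p_zero = 0.9, geom_prob = 0.5),
      other = list(type = "nbinom", size = 21, mu = 4.1)
    ),
    stereotype = c(IGHV11 = "CMRYGNYWYFDVW", IGHV12 = "CARWDGYYAMDYW"),
    p_stereotype = 0.9,
    cdr3_len_range = c(10, 16),
    # wild-type polyclonal background: rank-Zipf with lognormal jitter,
    # calibrated so pooled top-10 fractions have median ~1.5% and max < 5%
    wt_background = list(n_clones = 170, alpha = 0.42, sdlog = 0.08),
    # TCL1 miscellaneous background reuses the same law scaled to the
    # fraction mass left by the CLL clones
    bg_clones_tcl1 = 120,
    survival_median = list(
      subgroup = c(IGHV1 = 322, IGHV11 = 371, IGHV12 = 334, other = 345),
      subgroup_sex = c(IGHV1.F = 308, IGHV1.M = 344,
                       IGHV11.F = 378, IGHV11.M = 364),
      sex = c(M = 355, F = 337)
    ),
    survival_sdlog = survival_sdlog,
    censor_fraction = 0,
    total_reads = total_reads,
    n_longitudinal = n_longitudinal,
    longitudinal = list(k = 0.03, t0_before_end = 120, interval = 30,
                        first_age = 60),
    n_ln_pairs = n_ln_pairs,
    p_ln_switch_ighv11 = 4 / 9,
    ln_size = list(median = c(IGHV1 = 4.5, IGHV11 = 2.6, IGHV12 = 3.0,
                              other = 3.0),
                   sdlog = c(IGHV1 = 0.38, IGHV11 = 0.29, IGHV12 = 0.30,
                             other = 0.30))
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(spec))
  if (length(unknown)) {
    stop("unknown cohort_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec[names(override)] <- override
  .validate_spec(structure(spec, class = "cohort_spec"))
}

.validate_spec <- function(spec) {
  if (abs(sum(spec$clonality_mix) - 1) > 1e-9) {
    stop("clonality_mix must sum to 1", call. = FALSE)
  }
  if (abs(sum(spec$subgroup_mix) - 1) > 1e-9) {
    stop("subgroup_mix must sum to 1", call. = FALSE)
  }
  if (any(spec$p_female < 0 | spec$p_female > 1)) {
    stop("p_female must lie in [0, 1]", call. = FALSE)
  }
  if (any(unlist(spec$survival_median) <= 0)) {
    stop("survival medians must be positive", call. = FALSE)
  }
  spec
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d TCL1 + %d WT mice; clonality %s; subgroups %s\n",
              x$n_tcl1, x$n_wt,
              paste(sprintf("%s %.0f%%", names(x$clonality_mix),
                            100 * x$clonality_mix), collapse = "/"),
              paste(sprintf("%s %.0f%%", names(x$subgroup_mix),
                            100 * x$subgroup_mix), collapse = "/")))
  invisible(x)
}

# ---- low-level draws (all assume the caller set the RNG state) ----------

.random_cdr3 <- function(len_range) {
  len <- sample(len_range[1]:len_range[2], 1)
  paste0("C", paste(sample(.aa_alphabet, len - 2, replace = TRUE),
                    collapse = ""),
         sample(c("W", "W", "W", "F"), 1))
}

# mutate one interior position; used to resolve within-mouse CDR3 clashes
# and to model near-stereotype variants
.point_variant <- function(aa) {
  pos <- sample(2:(nchar(aa) - 1), 1)
  old <- substr(aa, pos, pos)
  substr(aa, pos, pos) <- sample(setdiff(.aa_alphabet, old), 1)
  aa
}

.random_nt <- function(aa) {
  paste(sample(c("A", "C", "G", "T"), 3 * nchar(aa), replace = TRUE),
        collapse = "")
}

.draw_insertions <- function(model, n) {
  switch(model$type,
    nbinom = stats::rnbinom(n, size = model$size, mu = model$mu),
    zero_tail = ifelse(stats::runif(n) < model$p_zero, 0L,
                       1L + stats::rgeom(n, model$geom_prob)),
    stop("unknown insertion model type: ", model$type, call. = FALSE)
  )
}

# rank-Zipf fraction vector with lognormal jitter, renormalized
.zipf_fractions <- function(n_clones, alpha, sdlog) {
  w <- seq_len(n_clones)^(-alpha) * stats::rlnorm(n_clones, 0, sdlog)
  sort(w / sum(w), decreasing = TRUE)
}

.other_subgroups <- c("IGHV2", "IGHV3", "IGHV5", "IGHV9", "IGHV14")

# clone record rows, vectorized over clones; v_call gets a plausible
# allele suffix so that normalize_ighv() round-trips the subgroup
.make_clone_rows <- function(sample_id, subgroup, cdr3_aa, fraction,
                             n_ins, total_reads) {
  n <- length(cdr3_aa)
  n1 <- stats::rbinom(n, n_ins, 0.5)
  tibble::tibble(
    sample_id = sample_id,
    v_call = paste0(subgroup, "-", sample(1:12, n, replace = TRUE),
                    "*0", sample(1:2, n, replace = TRUE)),
    v_gene = subgroup,
    d_gene = paste0("IGHD", sample(1:4, n, replace = TRUE), "-",
                    sample(1:2, n, replace = TRUE)),
    j_gene = paste0("IGHJ", sample(1:4, n, replace = TRUE)),
    cdr3_aa = cdr3_aa,
    cdr3_nt = vapply(cdr3_aa, .random_nt, character(1), USE.NAMES = FALSE),
    read_count = pmax(1, round(fraction * total_reads)),
    n1_len = n1,
    n2_len = n_ins - n1,
    productive = TRUE,
    mean_quality = round(stats::runif(n, 32, 40), 1)
  )
}

# CDR3 for a CLL clone of a given subgroup, avoiding sequences already
# used in the same sample (identical CDR3s would merge on aggregation)
.cll_cdr3 <- function(spec, subgroup, used) {
  aa <- if (subgroup %in% names(spec$stereotype)) {
    base <- spec$stereotype[[subgroup]]
    if (stats::runif(1) < spec$p_stereotype) base else .point_variant(base)
  } else {
    .random_cdr3(spec$cdr3_len_range)
  }
  while (aa %in% used) aa <- .point_variant(aa)
  aa
}

# polyclonal background records: diverse CDR3s over a broad V-gene draw
.background_records <- function(spec, sample_id, mass, n_clones, used) {
  fr <- .zipf_fractions(n_clones, spec$wt_background$alpha,
                        spec$wt_background$sdlog) * mass
  aa <- vapply(seq_len(n_clones),
               function(i) .random_cdr3(spec$cdr3_len_range), character(1))
  clash <- duplicated(aa) | aa %in% used
  while (any(clash)) {
    aa[clash] <- vapply(seq_len(sum(clash)),
                        function(i) .random_cdr3(spec$cdr3_len_range),
                        character(1))
    clash <- duplicated(aa) | aa %in% used
  }
  .make_clone_rows(
    sample_id,
    sample(c("IGHV1", .other_subgroups), n_clones, replace = TRUE),
    aa, fr, .draw_insertions(spec$insertion_model$IGHV1, n_clones),
    spec$total_reads)
}

# CLL clone fractions for one mouse given clonality class and dominance;
# keeps every CLL clone safely above the 5% threshold (0.052 floor guards
# against read-count rounding) and leaves at least 2% background mass
.draw_cll_fractions <- function(spec, n_cll, dominant) {
  floor_f <- 0.052
  reserve <- 0.02
  if (dominant && n_cll == 10L) n_cll <- sample(3:9, 1)
  cap1 <- min(0.95, 1 - reserve - (floor_f + 0.003) * (n_cll - 1))
  f1 <- if (dominant) {
    0.5 + (cap1 - 0.5) * stats::rbeta(1, spec$dominant_beta[1],
                                      spec$dominant_beta[2])
  } else {
    stats::runif(1, min(0.10, cap1 - 0.001), min(0.45, cap1))
  }
  f <- f1
  if (n_cll > 1L) {
    for (k in 2:n_cll) {
      upper <- min(f[k - 1],
                   1 - reserve - sum(f) - floor_f * (n_cll - k))
      f <- c(f, stats::runif(1, floor_f, max(floor_f + 1e-6, upper)))
    }
  }
  f
}

# clone table of one TCL1 organ sample given its latent CLL structure
.tcl1_sample_records <- function(spec, sample_id, cll) {
  used <- character(0)
  aa <- character(nrow(cll))
  n_ins <- integer(nrow(cll))
  for (i in seq_len(nrow(cll))) {
    aa[i] <- if (is.na(cll$cdr3_aa[i])) .cll_cdr3(spec, cll$subgroup[i], used)
      else cll$cdr3_aa[i]
    used <- c(used, aa[i])
    model_key <- if (cll$subgroup[i] %in% names(spec$insertion_model))
      cll$subgroup[i] else "other"
    n_ins[i] <- .draw_insertions(spec$insertion_model[[model_key]], 1)
  }
  cll_rows <- .make_clone_rows(sample_id, cll$subgroup, aa, cll$fraction,
                               n_ins, spec$total_reads)
  bg <- .background_records(spec, sample_id, 1 - sum(cll$fraction),
                            spec$bg_clones_tcl1, used)
  list(records = dplyr::bind_rows(cll_rows, bg),
       cll = dplyr::mutate(cll, cdr3_aa = aa))
}

.lookup_survival_median <- function(spec, subgroup, sex) {
  sm <- spec$survival_median
  key <- paste(subgroup, sex, sep = ".")
  if (!is.na(sex) && key %in% names(sm$subgroup_sex)) {
    return(sm$subgroup_sex[[key]])
  }
  if (subgroup %in% names(sm$subgroup)) return(sm$subgroup[[subgroup]])
  if (!is.na(sex) && sex %in% names(sm$sex)) return(sm$sex[[sex]])
  stats::median(sm$subgroup)
}

#' Simulate survival times for assigned mice
#'
#' Event times are log-normal with the per-stratum median of the spec's
#' survival law: the (subgroup, sex)-specific median when the assignment
#' carries a sex, else the subgroup marginal median. By default no
#' administrative censoring is applied (follow-up to humane endpoint);
#' `spec$censor_fraction` censors that share of mice uniformly before
#' their event.
#'
#' @param spec A `cohort_spec`.
#' @param assignments Tibble with `mouse_id`, `subgroup` and optionally
#'   `sex` (`"M"`/`"F"`, `NA` allowed).
#' @param seed Integer seed.
#' @return Tibble with `mouse_id`, `time_days`, `event`, `stratum`.
#' @export
simulate_survival <- function(spec, assignments, seed) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("mouse_id", "subgroup") %in% names(assignments)))
  sex <- if ("sex" %in% names(assignments)) assignments$sex
    else rep(NA_character_, nrow(assignments))
  withr::with_seed(seed, {
    med <- mapply(.lookup_survival_median, assignments$subgroup, sex,
                  MoreArgs = list(spec = spec))
    t <- stats::rlnorm(nrow(assignments), log(med), spec$survival_sdlog)
    event <- rep(1, nrow(assignments))
    if (spec$censor_fraction > 0) {
      cens <- stats::runif(nrow(assignments)) < spec$censor_fraction
      t[cens] <- t[cens] * stats::runif(sum(cens))
      event[cens] <- 0
    }
    tibble::tibble(
      mouse_id = assignments$mouse_id,
      time_days = round(t),
      event = event,
      stratum = ifelse(is.na(sex), assignments$subgroup,
                       paste(assignments$subgroup, sex, sep = "."))
    )
  })
}

#' Simulate wild-type repertoires
#'
#' Polyclonal clone tables with no clone near the CLL threshold: fractions
#' follow the calibrated rank-Zipf background law.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return Named list of clone-record tibbles, one per WT mouse.
#' @export
simulate_wt <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    out <- lapply(seq_len(spec$n_wt), function(i) {
      id <- sprintf("WT%02d_SPL", i)
      .background_records(spec, id, 1, spec$wt_background$n_clones,
                          character(0))
    })
    names(out) <- vapply(out, function(x) x$sample_id[1], character(1))
    out
  })
}

#' Simulate a full cohort
#'
#' Generates, per TCL1 mouse: sex and dominant-clone subgroup, clonality
#' class, a spleen clone table (CLL clones plus polyclonal background),
#' survival time, and — for designated subsets — monthly longitudinal blood
#' repertoires with a logistically growing dominant clone and a paired
#' lymph-node repertoire with possible IGHV11-to-IGHV1 dominant-clone
#' switching and a subgroup-dependent LN size. Wild-type mice contribute
#' polyclonal spleen tables (and longitudinal draws). Identical
#' `(spec, seed)` input reproduces the output exactly.
#'
#' @param spec A `cohort_spec`.
#' @param seed Integer seed.
#' @return List with `samples` (named list of clone-record tibbles),
#'   `metadata` (per-sample tibble: `sample_id`, `mouse_id`, `genotype`,
#'   `sex`, `age_days`, `survival_days`, `event`, `organ`, `sample_date`,
#'   `ln_size_mm`) and `ground_truth` (per-mouse latent draws).
#' @export
simulate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    samples <- list()
    meta <- list()
    truth <- list()
    birth <- as.Date("2019-01-01")

    class_levels <- c(mono = 1L, bi = 2L, oligo = 0L)  # oligo drawn below
    for (i in seq_len(spec$n_tcl1)) {
      mouse_id <- sprintf("T%03d", i)
      subgroup <- sample(names(spec$subgroup_mix), 1,
                         prob = spec$subgroup_mix)
      dom_sub <- if (subgroup == "other") sample(.other_subgroups, 1)
        else subgroup
      sex <- if (stats::runif(1) < spec$p_female[[subgroup]]) "F" else "M"
      cls <- sample(names(spec$clonality_mix), 1,
                    prob = spec$clonality_mix)
      n_cll <- if (cls == "oligo") sample(3:10, 1) else class_levels[[cls]]
      dominant <- stats::runif(1) < spec$p_dominant
      fr <- .draw_cll_fractions(spec, n_cll, dominant)
      n_cll <- length(fr)
      # secondary CLL clones draw their own subgroup from the mixture
      subs <- c(dom_sub, vapply(seq_len(n_cll - 1), function(j) {
        s <- sample(names(spec$subgroup_mix), 1, prob = spec$subgroup_mix)
        if (s == "other") sample(.other_subgroups, 1) else s
      }, character(1)))
      cll <- tibble::tibble(subgroup = subs, fraction = fr,
                            cdr3_aa = NA_character_)
      sid <- paste0(mouse_id, "_SPL")
      gen <- .tcl1_sample_records(spec, sid, cll)
      samples[[sid]] <- gen$records

      med <- .lookup_survival_median(spec, subgroup, sex)
      surv <- round(stats::rlnorm(1, log(med), spec$survival_sdlog))
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, mouse_id = mouse_id, genotype = "TCL1", sex = sex,
        age_days = surv, survival_days = surv, event = 1L, organ = "SPL",
        sample_date = birth + surv, ln_size_mm = NA_real_)
      truth[[mouse_id]] <- tibble::tibble(
        mouse_id = mouse_id, genotype = "TCL1", sex = sex,
        subgroup = subgroup, dominant_subgroup = dom_sub,
        clonality_class = c(mono = "monoclonal", bi = "biclonal",
                            oligo = "oligoclonal")[[cls]],
        n_cll = n_cll, dominant = dominant,
        dominant_fraction = fr[1],
        dominant_cdr3 = gen$cll$cdr3_aa[1],
        survival_days = surv, event = 1L)
    }
    truth <- dplyr::bind_rows(truth)

    # --- paired lymph-node repertoires --------------------------------
    dom_mice <- truth$mouse_id[truth$dominant]
    # favour IGHV1/IGHV11 dominants, as in a lymphadenopathy sub-study
    pref <- truth$mouse_id[truth$dominant &
                             truth$subgroup %in% c("IGHV1", "IGHV11")]
    ln_ids <- utils::head(c(pref, setdiff(dom_mice, pref)),
                          spec$n_ln_pairs)
    for (mouse_id in ln_ids) {
      tr <- truth[truth$mouse_id == mouse_id, ]
      spl_sub <- tr$dominant_subgroup
      switch_it <- spl_sub == "IGHV11" &&
        stats::runif(1) < spec$p_ln_switch_ighv11
      ln_sub <- if (switch_it) "IGHV1" else spl_sub
      n_extra <- sample(0:2, 1)
      fr <- .draw_cll_fractions(spec, 1L + n_extra, dominant = TRUE)
      subs <- c(ln_sub, rep(spl_sub, length(fr) - 1))
      # the concordant dominant clone keeps its spleen CDR3
      cll <- tibble::tibble(
        subgroup = subs, fraction = fr,
        cdr3_aa = c(if (switch_it) NA_character_ else tr$dominant_cdr3,
                    rep(NA_character_, length(fr) - 1)))
      sid <- paste0(mouse_id, "_LN")
      gen <- .tcl1_sample_records(spec, sid, cll)
      samples[[sid]] <- gen$records
      size_key <- if (ln_sub %in% names(spec$ln_size$median)) ln_sub
        else "other"
      ln_mm <- round(stats::rlnorm(1, log(spec$ln_size$median[[size_key]]),
                                   spec$ln_size$sdlog[[size_key]]), 1)
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, mouse_id = mouse_id, genotype = "TCL1",
        sex = tr$sex, age_days = tr$survival_days,
        survival_days = tr$survival_days, event = 1L, organ = "LN",
        sample_date = birth + tr$survival_days, ln_size_mm = ln_mm)
    }

    # --- longitudinal blood draws (TCL1): logistic dominant-clone growth
    long_ids <- utils::head(truth$mouse_id[truth$dominant],
                            spec$n_longitudinal)
    lp <- spec$longitudinal
    for (mouse_id in long_ids) {
      tr <- truth[truth$mouse_id == mouse_id, ]
      ages <- seq(lp$first_age, tr$survival_days - 1, by = lp$interval)
      t0 <- tr$survival_days - lp$t0_before_end
      for (age in ages) {
        f_dom <- tr$dominant_fraction / (1 + exp(-lp$k * (age - t0)))
        f_dom <- max(f_dom, 0.005)
        sid <- sprintf("%s_PB%03d", mouse_id, age)
        dom_row <- .make_clone_rows(
          sid, tr$dominant_subgroup, tr$dominant_cdr3, f_dom,
          .draw_insertions(spec$insertion_model[[
            if (tr$dominant_subgroup %in% names(spec$insertion_model))
              tr$dominant_subgroup else "other"]], 1),
          spec$total_reads)
        bg <- .background_records(spec, sid, 1 - f_dom, 80, tr$dominant_cdr3)
        samples[[sid]] <- dplyr::bind_rows(dom_row, bg)
        meta[[sid]] <- tibble::tibble(
          sample_id = sid, mouse_id = mouse_id, genotype = "TCL1",
          sex = tr$sex, age_days = age, survival_days = tr$survival_days,
          event = 1L, organ = "blood", sample_date = birth + age,
          ln_size_mm = NA_real_)
      }
    }

    # --- wild-type mice ----------------------------------------------
    for (i in seq_len(spec$n_wt)) {
      mouse_id <- sprintf("W%03d", i)
      sid <- paste0(mouse_id, "_SPL")
      sex <- if (stats::runif(1) < 0.62) "F" else "M"
      age <- round(stats::runif(1, 250, 400))
      samples[[sid]] <- .background_records(
        spec, sid, 1, spec$wt_background$n_clones, character(0))
      meta[[sid]] <- tibble::tibble(
        sample_id = sid, mouse_id = mouse_id, genotype = "WT", sex = sex,
        age_days = age, survival_days = age, event = 0L, organ = "SPL",
        sample_date = birth + age, ln_size_mm = NA_real_)
      truth <- dplyr::bind_rows(truth, tibble::tibble(
        mouse_id = mouse_id, genotype = "WT", sex = sex,
        subgroup = NA_character_, dominant_subgroup = NA_character_,
        clonality_class = "polyclonal_excess", n_cll = 0L,
        dominant = FALSE, dominant_fraction = NA_real_,
        dominant_cdr3 = NA_character_, survival_days = age, event = 0L))
    }

    list(samples = samples, metadata = dplyr::bind_rows(meta),
         ground_truth = truth)
  })
}

#' Write a simulated cohort to a directory
#'
#' Emits one AIRR Rearrangement TSV per sample plus `metadata.tsv` and
#' `ground_truth.tsv`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @param dialect Clone-table dialect to write.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = c("airr", "mixcr")) {
  dialect <- match.arg(dialect)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(cohort$samples)) {
    organ <- cohort$metadata$organ[cohort$metadata$sample_id == sid][1]
    rep <- aggregate_repertoire(cohort$samples[[sid]], sid, organ)
    write_clone_table(rep, file.path(dir, paste0(sid, ".tsv")), dialect)
  }
  readr::write_tsv(cohort$metadata, file.path(dir, "metadata.tsv"),
                   na = "", progress = FALSE)
  readr::write_tsv(cohort$ground_truth, file.path(dir, "ground_truth.tsv"),
                   na = "", progress = FALSE)
  invisible(dir)
}
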