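#' Simulation configuration
#'
#' Generative parameters for synthetic references, read sets and counts.
#' The model: per-mature relative abundances are log-normal; the case
#' condition's abundances are multiplied by a per-mature fold change and
#' renormalized; per-sample per-mature counts are negative binomial with
#' mean `depth * p` and the configured `dispersion` (size; `Inf`
#' degenerates to Poisson); each counted read draws its 5' and 3' offsets
#' from per-condition categorical distributions and is emitted as the
#' corresponding hairpin subsequence, optionally with per-base sequencing
#' error.
#'
#' @param n_hairpins Number of hairpins (one mature each).
#' @param conditions Tibble with `condition` and `n_replicates` columns;
#'   the first condition is treated as control by downstream helpers.
#' @param depth Expected classified reads per sample.
#' @param mature_len Mature length in nt (default 22).
#' @param flank_len Flank length on each side of the mature (default 10;
#'   must be at least `max_shift + 2` so every programmed extension is
#'   templated).
#' @param abundance_meanlog,abundance_sdlog Log-normal abundance
#'   parameters (defaults 0 and 1.5, spanning roughly four orders of
#'   magnitude as observed across real miRNA RPM tables).
#' @param foldchange Named numeric vector (mature id -> case/control
#'   ratio); unnamed matures default to 1.
#' @param offset5_dist,offset3_dist Per-condition offset distributions: a
#'   named list by condition; each element is a named list with a
#'   `.default` probability vector (names are signed offsets) and
#'   optional per-mature overrides. `NULL` means a point mass at 0.
#' @param dispersion Negative-binomial size (default 20, moderate
#'   overdispersion); `Inf` gives Poisson counts.
#' @param seq_error_rate Per-base substitution error rate (default 0 so
#'   classification recovery is exact).
#' @param max_shift Largest offset magnitude the reference generator must
#'   keep unambiguous (default 5, matching the classifier default).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_hairpins = 100L,
                       conditions = tibble(condition = c("control", "case"),
                                           n_replicates = c(4L, 5L)),
                       depth = 1e5, mature_len = 22L, flank_len = 10L,
                       abundance_meanlog = 0, abundance_sdlog = 1.5,
                       foldchange = NULL,
                       offset5_dist = NULL, offset3_dist = NULL,
                       dispersion = 20, seq_error_rate = 0,
                       max_shift = 5L) {
  conditions <- as_tibble(conditions)
  stopifnot(all(c("condition", "n_replicates") %in% names(conditions)))
  if (any(conditions$n_replicates < 1L)) {
    stopf("isomirq_bad_config", "replicate counts must be >= 1")
  }
  if (depth <= 0) stopf("isomirq_bad_config", "depth must be > 0")
  if (flank_len < max_shift + 2L) {
    stopf("isomirq_bad_config",
          "flank_len must be >= max_shift + 2 (%d), got %d",
          max_shift + 2L, flank_len)
  }
  cfg <- list(n_hairpins = as.integer(n_hairpins), conditions = conditions,
              depth = depth, mature_len = as.integer(mature_len),
              flank_len = as.integer(flank_len),
              abundance_meanlog = abundance_meanlog,
              abundance_sdlog = abundance_sdlog,
              foldchange = foldchange,
              offset5_dist = offset5_dist, offset3_dist = offset3_dist,
              dispersion = dispersion, seq_error_rate = seq_error_rate,
              max_shift = as.integer(max_shift))
  validate_offset_dists(cfg$offset5_dist, flank_len)
  validate_offset_dists(cfg$offset3_dist, flank_len)
  structure(cfg, class = "sim_config")
}

validate_offset_dists <- function(d, flank_len) {
  if (is.null(d)) return(invisible(TRUE))
  for (cond in names(d)) {
    for (p in d[[cond]]) {
      if (abs(sum(p) - 1) > 1e-8) {
        stopf("isomirq_bad_config",
              "offset probabilities must sum to 1 (condition '%s')", cond)
      }
      offs <- as.integer(names(p))
      if (any(is.na(offs)) || any(abs(offs) > flank_len)) {
        stopf("isomirq_bad_config",
              "offset names must be integers within the flank length")
      }
    }
  }
  invisible(TRUE)
}

# Offset distribution lookup with a .default fallback; point mass at 0
# when the whole structure is NULL.
offset_dist_for <- function(d, condition, mature_id) {
  if (is.null(d)) return(c(`0` = 1))
  dc <- d[[condition]]
  if (is.null(dc)) return(c(`0` = 1))
  dc[[mature_id]] %||% dc[[".default"]] %||% c(`0` = 1)
}

#' Generate a synthetic hairpin reference
#'
#' Each hairpin is `flank + mature + flank` with uniform-random ACGU
#' bases, so every 5'/3' offset up to the flank length is templated.
#' References are rejection-sampled so that all hairpin windows within
#' `max_shift` of any mature are globally unique strings, i.e. no read
#' generated within the offset range can map to two matures.
#'
#' @inheritParams sim_config
#' @param seed Optional seed (`NULL` leaves the RNG stream untouched).
#' @param max_attempts Resampling attempts before giving up.
#' @return An `isomir_ref` tibble (mature ids `syn-mir-001`, ...).
#' @export
make_reference <- function(n_hairpins = 100L, mature_len = 22L,
                           flank_len = 10L, max_shift = 5L, seed = NULL,
                           max_attempts = 20L) {
  seed_guard(seed)
  n <- as.integer(n_hairpins)
  hp_len <- mature_len + 2L * flank_len
  rand_seq <- function(k) {
    paste(sample(c("A", "C", "G", "U"), k, replace = TRUE), collapse = "")
  }
  seqs <- vapply(seq_len(n), function(i) rand_seq(hp_len), "")
  cfg <- classifier_config(max_shift = max_shift)
  build_ref <- function(seqs) {
    ref <- tibble(
      hairpin_id = sprintf("syn-hp-%03d", seq_len(n)),
      hairpin_seq = seqs,
      mature_id = sprintf("syn-mir-%03d", seq_len(n)),
      start = as.integer(flank_len),
      end = as.integer(flank_len + mature_len),
      arm = "5p"
    ) |>
      mutate(mature_seq = substr(.data$hairpin_seq, .data$start + 1L,
                                 .data$end))
    class(ref) <- c("isomir_ref", class(ref))
    ref
  }
  for (attempt in seq_len(max_attempts)) {
    ref <- build_ref(seqs)
    wins <- candidate_windows(ref, cfg)
    dup <- wins$window[duplicated(wins$window)]
    if (!length(dup)) return(ref)
    offenders <- unique(wins$mature_id[wins$window %in% dup])
    idx <- match(offenders, ref$mature_id)
    seqs[idx] <- vapply(idx, function(i) rand_seq(hp_len), "")
  }
  stopf("isomirq_rejection_failure",
        "could not build an unambiguous reference in %d attempts",
        max_attempts)
}

#' Simulate per-sample per-mature counts
#'
#' Draws log-normal relative abundances, applies the per-mature fold
#' change to the non-control conditions, renormalizes, and draws negative
#' binomial counts with mean `depth * p`.
#'
#' @param config A [sim_config()].
#' @param ref An `isomir_ref` (supplies the mature ids).
#' @param seed Optional seed.
#' @return A list with `counts` (long tibble: `sample_id`, `condition`,
#'   `mature_id`, `mu`, `count`), `design` and `truth_abundance`
#'   (per-mature relative abundance per condition and fold change).
#' @export
simulate_counts <- function(config, ref, seed = NULL) {
  seed_guard(seed)
  ids <- ref$mature_id
  n <- length(ids)
  x <- rlnorm(n, config$abundance_meanlog, config$abundance_sdlog)
  fc <- rep(1, n)
  names(fc) <- ids
  if (!is.null(config$foldchange)) {
    common <- intersect(names(config$foldchange), ids)
    fc[common] <- config$foldchange[common]
  }
  control <- config$conditions$condition[1]
  design <- config$conditions |>
    purrr::pmap(function(condition, n_replicates) {
      tibble(sample_id = sprintf("%s_%d", condition,
                                 seq_len(n_replicates)),
             condition = condition)
    }) |>
    bind_rows()
  p_by_cond <- lapply(config$conditions$condition, function(cond) {
    w <- if (cond == control) x else x * fc
    w / sum(w)
  })
  names(p_by_cond) <- config$conditions$condition
  counts <- design |>
    purrr::pmap(function(sample_id, condition) {
      mu <- config$depth * p_by_cond[[condition]]
      cnt <- if (is.infinite(config$dispersion)) {
        rpois(n, mu)
      } else {
        rnbinom(n, mu = mu, size = config$dispersion)
      }
      tibble(sample_id = sample_id, condition = condition,
             mature_id = ids, mu = mu, count = as.integer(cnt))
    }) |>
    bind_rows()
  truth <- tibble(mature_id = ids, foldchange = unname(fc))
  for (cond in config$conditions$condition) {
    truth[[paste0("p_", cond)]] <- p_by_cond[[cond]]
  }
  list(counts = counts, design = design, truth_abundance = truth)
}

#' Simulate collapsed read sets from counts
#'
#' Each unit count draws a `(offset5, offset3)` pair from the condition's
#' categorical distributions and is emitted as the corresponding hairpin
#' window; per-base substitution errors are applied at
#' `seq_error_rate`; identical sequences are collapsed per sample. The
#' returned truth table records every emitted read (post-error sequence)
#' with its source mature and offsets, and reconciles exactly with the
#' simulated counts.
#'
#' @param sim Output of [simulate_counts()].
#' @param ref The `isomir_ref` used to build the counts.
#' @param config The same [sim_config()].
#' @param seed Optional seed.
#' @return A list with `read_sets` (named list of `sequence`/`count`
#'   tibbles, one per sample) and `truth_reads` (tibble `sample_id`,
#'   `mature_id`, `offset5`, `offset3`, `sequence`, `count`).
#' @export
simulate_reads <- function(sim, ref, config, seed = NULL) {
  seed_guard(seed)
  cfgc <- classifier_config(max_shift = max(config$max_shift, 2L))
  wins <- candidate_windows(ref, cfgc)
  key <- paste(wins$mature_id, wins$offset5, wins$offset3)
  win_of <- setNames(wins$window, key)

  emit_sample <- function(d) {
    rows <- vector("list", nrow(d))
    for (i in seq_len(nrow(d))) {
      nct <- d$count[i]
      if (nct == 0L) next
      mid <- d$mature_id[i]
      p5 <- offset_dist_for(config$offset5_dist, d$condition[i], mid)
      p3 <- offset_dist_for(config$offset3_dist, d$condition[i], mid)
      # outer(p3, p5) vectorizes with o3 fastest; expand_grid varies the
      # last column fastest, so list o5 first.
      grid <- tidyr::expand_grid(o5 = as.integer(names(p5)),
                                 o3 = as.integer(names(p3)))
      pr <- as.vector(outer(unname(p3), unname(p5)))
      draw <- rmultinom(1, nct, pr)[, 1]
      keep <- draw > 0L
      if (!any(keep)) next
      sq <- win_of[paste(mid, grid$o5[keep], grid$o3[keep])]
      if (anyNA(sq)) {
        stopf("isomirq_offset_out_of_range",
              "programmed offset incompatible with flank length for %s",
              mid)
      }
      rows[[i]] <- tibble(mature_id = mid, offset5 = grid$o5[keep],
                          offset3 = grid$o3[keep], sequence = unname(sq),
                          count = as.integer(draw[keep]))
    }
    bind_rows(rows)
  }

  apply_errors <- function(truth, rate) {
    if (rate <= 0 || nrow(truth) == 0L) return(truth)
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      len <- nchar(row$sequence)
      p_err <- 1 - (1 - rate)^len
      k <- rbinom(1, row$count, p_err)
      clean <- row
      clean$count <- row$count - k
      muts <- NULL
      if (k > 0L) {
        alphabet <- c("A", "C", "G", "U")
        mut_seqs <- vapply(seq_len(k), function(j) {
          ch <- strsplit(row$sequence, "")[[1]]
          hit <- which(runif(len) < rate)
          if (!length(hit)) hit <- sample.int(len, 1L)
          for (h in hit) {
            ch[h] <- sample(setdiff(alphabet, ch[h]), 1L)
          }
          paste(ch, collapse = "")
        }, "")
        muts <- tibble(mature_id = row$mature_id, offset5 = row$offset5,
                       offset3 = row$offset3, sequence = mut_seqs,
                       count = 1L)
      }
      out[[i]] <- bind_rows(if (clean$count > 0L) clean, muts)
    }
    bind_rows(out)
  }

  samples <- split(sim$counts, sim$counts$sample_id)
  truth_list <- lapply(sim$design$sample_id, function(sid) {
    t <- emit_sample(samples[[sid]])
    t <- apply_errors(t, config$seq_error_rate)
    if (nrow(t)) t$sample_id <- sid
    t
  })
  names(truth_list) <- sim$design$sample_id
  read_sets <- purrr::imap(truth_list, function(t, sid) {
    cond <- sim$design$condition[sim$design$sample_id == sid]
    rs <- if (nrow(t) == 0L) {
      tibble(sequence = character(), count = integer())
    } else {
      t |>
        group_by(.data$sequence) |>
        summarise(count = sum(.data$count), .groups = "drop") |>
        arrange(.data$sequence)
    }
    attr(rs, "sample_id") <- sid
    attr(rs, "condition") <- cond
    attr(rs, "total_input_reads") <- sum(rs$count)
    rs
  })
  truth_reads <- bind_rows(truth_list) |>
    group_by(.data$sample_id, .data$mature_id, .data$offset5,
             .data$offset3, .data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop")
  list(read_sets = read_sets, truth_reads = truth_reads)
}

#' Packaged global miRNA-depletion scenario
#'
#' A full demo dataset emulating loss of Microprocessor activity: 100
#' matures across 4 control and 5 case replicates; 95% of matures are
#' programmed at least 2-fold down in the case condition; a designated
#' 3-mature cluster stays level or slightly up and gains case-condition
#' 5'-offset mass at +1/+2 nt (upstream cleavage), mimicking processing
#' by an alternative nuclease; 2 matures are unchanged. Deterministic
#' under the seed.
#'
#' @param seed Integer seed.
#' @param n_matures Number of matures (default 100).
#' @param depth Expected classified reads per sample (default 1e5).
#' @param dispersion NB size (default 20).
#' @return A list: `reference`, `config`, `design`, `counts` (the
#'   [simulate_counts()] output), `read_sets`, `truth` (abundance truth,
#'   read-level truth, `frac_down`, `cluster_matures`).
#' @export
drosha_loss_scenario <- function(seed = 1L, n_matures = 100L,
                                 depth = 1e5, dispersion = 20) {
  seed_guard(seed)
  n_cluster <- min(3L, n_matures)
  n_stable <- min(2L, max(n_matures - n_cluster, 0L))
  ids <- sprintf("syn-mir-%03d", seq_len(n_matures))
  cluster <- ids[seq_len(n_cluster)]
  stable <- ids[n_cluster + seq_len(n_stable)]
  down <- setdiff(ids, c(cluster, stable))
  fc <- setNames(rep(1, n_matures), ids)
  fc[down] <- runif(length(down), 0.1, 0.5)
  fc[cluster] <- runif(length(cluster), 1.1, 1.6)

  ctrl_dist <- c(`-1` = 0.05, `0` = 0.95)
  case_cluster <- c(`-1` = 0.05, `0` = 0.55, `1` = 0.2, `2` = 0.2)
  offset5_dist <- list(
    control = list(.default = ctrl_dist),
    case = c(list(.default = ctrl_dist),
             setNames(rep(list(case_cluster), length(cluster)), cluster))
  )
  config <- sim_config(n_hairpins = n_matures, depth = depth,
                       dispersion = dispersion, foldchange = fc,
                       offset5_dist = offset5_dist)
  reference <- make_reference(n_matures, config$mature_len,
                              config$flank_len, config$max_shift)
  sim <- simulate_counts(config, reference)
  reads <- simulate_reads(sim, reference, config)
  list(reference = reference, config = config, design = sim$design,
       counts = sim, read_sets = reads$read_sets,
       truth = list(abundance = sim$truth_abundance,
                    reads = reads$truth_reads,
                    frac_down = length(down) / n_matures,
                    cluster_matures = cluster))
}

#' Write a simulated scenario to disk in the package's file dialects
#'
#' Emits `hairpins.fa`, `annotation.tsv`, one collapsed FASTA per sample,
#' `design.tsv` (with relative paths), `truth_reads.tsv`,
#' `truth_abundance.tsv` and `config.yaml`.
#'
#' @param scenario Output of [drosha_loss_scenario()] (or a list with the
#'   same elements).
#' @param dir Output directory (created if needed).
#' @return The design file path, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_reference(scenario$reference, file.path(dir, "hairpins.fa"),
                  file.path(dir, "annotation.tsv"))
  design <- scenario$design
  design$path <- sprintf("%s.fa", design$sample_id)
  design$format <- "collapsed_fasta"
  for (sid in design$sample_id) {
    write_reads(scenario$read_sets[[sid]], file.path(dir, sprintf("%s.fa",
                                                                  sid)))
  }
  readr::write_tsv(design, file.path(dir, "design.tsv"))
  readr::write_tsv(scenario$truth$reads, file.path(dir, "truth_reads.tsv"))
  readr::write_tsv(scenario$truth$abundance,
                   file.path(dir, "truth_abundance.tsv"))
  write_sim_config(scenario$config, file.path(dir, "config.yaml"))
  invisible(file.path(dir, "design.tsv"))
}

#' Serialize / read a simulation configuration as YAML
#'
#' @param config A [sim_config()].
#' @param path YAML file path.
#' @return `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$conditions <- as.list(as.data.frame(x$conditions))
  x$foldchange <- as.list(x$foldchange)
  # named numeric vectors lose their names as YAML sequences; emit maps
  x$offset5_dist <- lapply(x$offset5_dist,
                           function(cond) lapply(cond, as.list))
  x$offset3_dist <- lapply(x$offset3_dist,
                           function(cond) lapply(cond, as.list))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  fc <- unlist(x$foldchange)
  o5 <- lapply(x$offset5_dist, function(cond) lapply(cond, unlist))
  o3 <- lapply(x$offset3_dist, function(cond) lapply(cond, unlist))
  sim_config(
    n_hairpins = x$n_hairpins,
    conditions = tibble(condition = x$conditions$condition,
                        n_replicates = as.integer(
                          x$conditions$n_replicates)),
    depth = x$depth, mature_len = x$mature_len, flank_len = x$flank_len,
    abundance_meanlog = x$abundance_meanlog,
    abundance_sdlog = x$abundance_sdlog,
    foldchange = fc,
    offset5_dist = if (length(o5)) o5 else NULL,
    offset3_dist = if (length(o3)) o3 else NULL,
    dispersion = if (is.character(x$dispersion) ||
                     is.null(x$dispersion)) Inf else x$dispersion,
    seq_error_rate = x$seq_error_rate, max_shift = x$max_shift
  )
}

#' Simulate bench-assay measurement tables with known truth
#'
#' Generates (i) a long qPCR Ct table with programmed fold changes and
#' Gaussian cycle noise, in triplicate, against a constant-Ct reference
#' target; (ii) IVP band intensities with known processing activities;
#' (iii) growth curves sampled at 8-40 h from programmed doubling times
#' with log-normal count noise.
#'
#' @param seed Integer seed.
#' @param folds Named programmed fold changes (case vs control) for the
#'   qPCR targets.
#' @param ct_noise_sd Gaussian Ct noise, cycles (default 0.1).
#' @param td_truth Named programmed doubling times in hours.
#' @param growth_sigma Log-normal noise sd on counts (default 0.05).
#' @return A list with tibbles `ct`, `ivp`, `growth` and a `truth` list.
#' @export
simulate_assays <- function(seed = 1L,
                            folds = c(target_down = 0.1,
                                      target_flat = 1,
                                      target_up = 16),
                            ct_noise_sd = 0.1,
                            td_truth = c(fl_10pct = 20, fl_1pct = 56,
                                         dn_10pct = 21, dn_1pct = 21),
                            growth_sigma = 0.05) {
  seed_guard(seed)
  ct_ref <- 15
  ct_base <- 24
  ct <- tidyr::expand_grid(
    sample = c("control", "case"),
    target = c(names(folds), "reference"),
    replicate = 1:3
  ) |>
    mutate(ct = ifelse(
      .data$target == "reference", ct_ref,
      ct_base - ifelse(.data$sample == "case",
                       log2(folds[.data$target]), 0)
    ) + rnorm(n(), 0, ct_noise_sd))

  ivp <- tibble(
    sample = c("fl", "dn"),
    pre_signal = c(5, 1.5),
    pri_signal = c(5, 8.5),
    protein_amount = c(1, 1)
  )
  ivp_truth <- (ivp$pre_signal / (ivp$pre_signal + ivp$pri_signal)) /
    ivp$protein_amount

  times <- c(8, 16, 24, 32, 40)
  growth <- tidyr::expand_grid(sample = names(td_truth), time = times) |>
    mutate(count = 1e5 * 2^(.data$time / td_truth[.data$sample]) *
             exp(rnorm(n(), 0, growth_sigma)))

  list(ct = ct, ivp = ivp, growth = growth,
       truth = list(folds = folds, td = td_truth,
                    ivp_activity = setNames(ivp_truth, ivp$sample),
                    ct_reference = ct_ref))
}
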