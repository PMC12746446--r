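#' Run configuration for an adaptive-tempering TI calculation
#'
#' Collects the model, grid, sampler settings, component toggles, intervals,
#' and budget of a run. Defaults follow the reference protocol: 101 lambda
#' windows, 8 replicas, jump and exchange attempts every 100 steps, a
#' preliminary scan worth 2% of the budget (the analogue of a 500k-step scan
#' in a 2.5e7-step study), adaptation every 1e4 steps, and a 10% burn-in
#' discarded before estimation.
#'
#' @param model an [alchemical model][model_systems].
#' @param beta inverse temperature (1/kT).
#' @param n_windows number of lambda windows.
#' @param n_replicas number of concurrently run walkers.
#' @param total_steps total propagation budget summed over the scan and all
#'   replicas (honoured exactly).
#' @param var,re,aces component toggles: variance-adaptive resampling,
#'   replica exchange, torsion-scaling enhanced sampling.
#' @param aces_mapping `"two_state"` (physical/dummy exchange; the default)
#'   or `"direct"` (`gamma(lambda) = lambda`, no exchange).
#' @param jump_interval steps between lambda-jump attempts.
#' @param exchange_interval steps between exchange attempts (RE and gamma
#'   flips).
#' @param adaptation_interval total steps between bias/variance refreshes.
#' @param prescan_fraction fraction of the budget spent on the sequential
#'   scan.
#' @param sampler,step_size,record_interval passed to [propagate()].
#' @param jump_rule passed to [heat_bath_jump()].
#' @param burn_in fraction of each replica's stream discarded before
#'   estimation (in `[0, 0.5]`).
#' @param min_samples,floor_frac passed to [target_probabilities()].
#' @param seed master seed; all streams derive from it.
#' @return an object of class `run_config`.
#' @export
run_config <- function(model = harmonic_model(), beta = 1, n_windows = 101L,
                       n_replicas = 8L, total_steps = 1e6, var = FALSE,
                       re = FALSE, aces = FALSE,
                       aces_mapping = c("two_state", "direct"),
                       jump_interval = 100L, exchange_interval = 100L,
                       adaptation_interval = 10000L,
                       prescan_fraction = 0.02,
                       sampler = "metropolis", step_size = 0.5,
                       record_interval = 1L,
                       jump_rule = c("forced", "metropolized"),
                       burn_in = 0.10, min_samples = 10L, floor_frac = 0.1,
                       seed = 1L) {
  aces_mapping <- match.arg(aces_mapping)
  jump_rule <- match.arg(jump_rule)
  stopifnot(inherits(model, "alchemical_model"), beta > 0,
            jump_interval >= 1, exchange_interval >= 1,
            adaptation_interval >= 1, record_interval >= 1,
            burn_in >= 0, burn_in <= 0.5, n_replicas >= 1,
            prescan_fraction >= 0, prescan_fraction < 1)
  if (aces && !isTRUE(model$has_torsions))
    stop("torsion-scaling enhanced sampling requires a model with torsions",
         call. = FALSE)
  structure(
    list(model = model, beta = beta, n_windows = as.integer(n_windows),
         n_replicas = as.integer(n_replicas), total_steps = total_steps,
         var = var, re = re, aces = aces, aces_mapping = aces_mapping,
         jump_interval = as.integer(jump_interval),
         exchange_interval = as.integer(exchange_interval),
         adaptation_interval = as.integer(adaptation_interval),
         prescan_fraction = prescan_fraction, sampler = sampler,
         step_size = step_size, record_interval = as.integer(record_interval),
         jump_rule = jump_rule, burn_in = burn_in,
         min_samples = as.integer(min_samples), floor_frac = floor_frac,
         seed = as.integer(seed)),
    class = "run_config")
}

#' @rdname run_config
#' @export
method_label <- function(config) {
  lab <- "ST"
  if (config$var) lab <- paste0(lab, "+VAR")
  if (config$re) lab <- paste0(lab, "+RE")
  if (config$aces) {
    n_sc <- sum(config$model$parameters$scaled)
    lab <- paste0(lab, if (n_sc > 1) "+mACES" else "+sACES")
  }
  lab
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run config> %s on '%s': %d windows, %d replicas, %g steps\n",
              method_label(x), x$model$name, x$n_windows, x$n_replicas,
              x$total_steps))
  invisible(x)
}

derive_seeds <- function(master, n) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old))
  set.seed(master)
  sample.int(.Machine$integer.max - 1L, n)
}

replica_start_windows <- function(n_replicas, n_windows) {
  if (n_replicas == 1) return(1L)
  as.integer(round((seq_len(n_replicas) - 1) * (n_windows - 1) /
                     (n_replicas - 1)) + 1)
}

#' Run the full adaptive serial-tempering calculation
#'
#' Executes the master loop: lambda-grid initialisation, sequential prescan,
#' initial Simpson bias and variance estimates, replica launch at evenly
#' spread windows, then interleaved propagation / lambda jumps / statistics
#' updates, with bias and target refreshes at the adaptation interval and
#' (optionally) replica-exchange and gamma-flip attempts at the exchange
#' interval. The final free energy is a thermodynamic integration of the
#' per-window mean `dU/dlambda` along the physical coordinate only, after
#' discarding the configured burn-in from each replica's stream.
#'
#' @param config a [run_config()].
#' @param keep_records return the full sample table (default TRUE).
#' @return an object of class `run_report`: method label, TI estimate with
#'   propagated and across-replicate uncertainties, per-window diagnostics,
#'   visitation histogram, jump/exchange logs and acceptance rates, the
#'   config echo and seed.
#' @export
run_samti <- function(config, keep_records = TRUE) {
  stopifnot(inherits(config, "run_config"))
  model <- config$model
  grid <- lambda_grid(config$n_windows)
  n_rep <- config$n_replicas
  seeds <- derive_seeds(config$seed, n_rep + 1L)

  # Phase 1: sequential scan seeds the bias and the variance tracker
  spw <- max(1L, as.integer(round(
    config$prescan_fraction * config$total_steps / grid$n_windows)))
  scan_state <- walker_state(model, lam_index = 1L, seed = seeds[1L])
  scan <- sequential_scan(scan_state, model, grid, spw, beta = config$beta,
                          step_size = config$step_size,
                          record_interval = config$record_interval,
                          sampler = config$sampler,
                          gamma_mapping = aces_gamma_mapping(config))
  bias <- build_bias_simpson(scan$means, grid)
  tracker <- variance_tracker(grid$n_windows)
  for (i in seq_len(grid$n_windows)) {
    w <- scan$records$lam_index == i
    tracker <- tracker_update(tracker, i, scan$records$dudl[w])
  }
  targets <- if (config$var)
    target_probabilities(tracker, config$min_samples, config$floor_frac)
  else NULL

  # replica launch
  start <- replica_start_windows(n_rep, grid$n_windows)
  walkers <- lapply(seq_len(n_rep), function(r)
    walker_state(model, lam_index = start[r], seed = seeds[r + 1L]))

  prescan_total <- spw * grid$n_windows
  budget <- floor(config$total_steps) - prescan_total
  if (budget < 0) stop("budget smaller than the prescan", call. = FALSE)
  per_rep <- rep(budget %/% n_rep, n_rep)
  if (budget %% n_rep > 0)
    per_rep[seq_len(budget %% n_rep)] <- per_rep[seq_len(budget %% n_rep)] + 1

  recs <- list(); jump_log <- list(); exch_log <- list()
  visit <- integer(grid$n_windows)
  done <- numeric(n_rep)
  steps_since_adapt <- 0
  round_i <- 0L
  while (any(done < per_rep)) {
    round_i <- round_i + 1L
    for (r in seq_len(n_rep)) {
      chunk <- min(config$jump_interval, per_rep[r] - done[r])
      if (chunk <= 0) next
      out <- propagate(walkers[[r]], model, grid, chunk, beta = config$beta,
                       step_size = config$step_size,
                       record_interval = config$record_interval,
                       sampler = config$sampler,
                       gamma_mapping = aces_gamma_mapping(config))
      walkers[[r]] <- out$state
      if (nrow(out$records)) {
        out$records$replica <- r
        recs[[length(recs) + 1L]] <- out$records
        if (out$records$gamma_state[1L] == "physical")
          tracker <- tracker_update(tracker, out$records$lam_index[1L],
                                    out$records$dudl)
      }
      done[r] <- done[r] + chunk
      steps_since_adapt <- steps_since_adapt + chunk

      # ST lambda jump
      lw <- jump_log_weights(walkers[[r]], model, grid, bias, config$beta)
      from <- walkers[[r]]$lam_index
      res <- with_stream(walkers[[r]]$rng_state, {
        if (config$var) {
          probs <- heat_bath_probabilities(lw, from)
          probs <- apply_var_weight(probs, targets, from)
          if (all(probs == 0)) from else sample.int(grid$n_windows, 1L,
                                                    prob = probs)
        } else {
          heat_bath_jump(lw, from, rule = config$jump_rule)
        }
      })
      walkers[[r]]$rng_state <- res$rng_state
      walkers[[r]]$lam_index <- res$value
      visit[res$value] <- visit[res$value] + 1L
      jump_log[[length(jump_log) + 1L]] <-
        c(replica = r, step = walkers[[r]]$step, from = from, to = res$value)
    }

    at_exchange <- (round_i * config$jump_interval) %%
      config$exchange_interval == 0
    if (config$aces && config$aces_mapping == "two_state" && at_exchange) {
      for (r in seq_len(n_rep)) {
        a <- aces_exchange_attempt(walkers[[r]], model, grid, config$beta)
        walkers[[r]] <- a$state
        exch_log[[length(exch_log) + 1L]] <-
          data.frame(kind = "gamma_flip", round = round_i, a = r, b = r,
                     delta_u = a$delta_u, accepted = a$accepted)
      }
    }
    if (config$re && n_rep >= 2 && at_exchange) {
      for (pr in pair_schedule(n_rep, round_i, "fixed")) {
        ex <- replica_exchange_attempt(walkers[[pr[1L]]], walkers[[pr[2L]]],
                                       model, grid, config$beta)
        walkers[[pr[1L]]] <- ex$state_m
        walkers[[pr[2L]]] <- ex$state_n
        exch_log[[length(exch_log) + 1L]] <-
          data.frame(kind = "replica_exchange", round = round_i,
                     a = pr[1L], b = pr[2L], delta_u = ex$delta_u,
                     accepted = ex$accepted)
      }
    }
    if (steps_since_adapt >= config$adaptation_interval) {
      steps_since_adapt <- 0
      m <- tracker_mean(tracker)
      if (!anyNA(m)) bias <- build_bias_simpson(m, grid)
      if (config$var)
        targets <- target_probabilities(tracker, config$min_samples,
                                        config$floor_frac)
    }
  }

  scan_recs <- scan$records
  scan_recs$replica <- 0L
  records <- bind_records(c(list(scan_recs), recs))
  finish_report(config, grid, records, visit,
                jump_log = as.data.frame(do.call(rbind, jump_log)),
                exch_log = if (length(exch_log)) do.call(rbind, exch_log),
                label = method_label(config), keep_records = keep_records,
                budget = list(prescan = prescan_total, main = sum(done),
                              total = prescan_total + sum(done)))
}

aces_gamma_mapping <- function(config) {
  if (config$aces && config$aces_mapping == "direct") "direct" else "fixed"
}

# burn-in, pooled and per-replica TI, diagnostics, report assembly.
# replicate_mode "walker" treats each walker as a replicate (the adaptive
# runs); "blocks" slices every window's stream into n_blocks contiguous
# time blocks (the fixed-window reference runs, where each walker pins a
# single window and walker-wise dG spread would be degenerate).
finish_report <- function(config, grid, records, visit = NULL,
                          jump_log = NULL, exch_log = NULL, label,
                          keep_records = TRUE,
                          replicate_mode = c("walker", "blocks"),
                          n_blocks = 8L, budget = NULL) {
  replicate_mode <- match.arg(replicate_mode)
  records <- apply_burn_in(records, config$burn_in)
  phys <- records[records$gamma_state == "physical", , drop = FALSE]
  n_w <- grid$n_windows
  wfac <- factor(phys$lam_index, levels = seq_len(n_w))
  by_win <- split(phys$dudl, wfac)
  pooled_n <- lengths(by_win)
  if (any(pooled_n == 0))
    stop("window(s) ", paste(which(pooled_n == 0), collapse = ", "),
         " have no physical-state samples after burn-in", call. = FALSE)
  pooled_means <- vapply(by_win, mean, numeric(1), USE.NAMES = FALSE)
  ti <- ti_integrate(pooled_means, grid)
  diag <- window_diagnostics(phys, grid)
  qw <- quadrature_weights(n_w, "simpson") * grid$delta_lambda
  g_pool <- ifelse(is.finite(diag$g), diag$g, 1)

  # per-replicate dG and propagated SE (pooled g per window; a replicate's
  # unvisited windows fall back to the pooled mean/sd)
  rep_group <- if (replicate_mode == "walker") {
    phys$replica
  } else {
    # contiguous time blocks within each window's stream
    blk <- integer(nrow(phys))
    for (idx in split(seq_len(nrow(phys)), wfac)) {
      n <- length(idx)
      blk[idx] <- pmin(n_blocks, 1L + ((seq_len(n) - 1L) * n_blocks) %/% n)
    }
    blk
  }
  reps <- setdiff(sort(unique(rep_group)), 0L)  # 0 = prescan walker
  if (!length(reps)) reps <- sort(unique(rep_group))
  rep_stats <- lapply(reps, function(r) {
    sel <- rep_group == r
    bw <- split(phys$dudl[sel], wfac[sel])
    nn <- lengths(bw)
    m <- vapply(bw, function(x) if (length(x)) mean(x) else NA_real_,
                numeric(1), USE.NAMES = FALSE)
    s <- vapply(bw, function(x) if (length(x) > 1) stats::sd(x) else NA_real_,
                numeric(1), USE.NAMES = FALSE)
    m[is.na(m)] <- pooled_means[is.na(m)]
    s[is.na(s)] <- diag$sd[is.na(s)]
    n_eff <- pmax(1, ifelse(nn > 0, nn, diag$n) / g_pool)
    c(dg = ti_integrate(m, grid)$dg,
      se = sqrt(sum(qw^2 * s^2 / n_eff, na.rm = TRUE)))
  })
  rep_dg <- vapply(rep_stats, `[[`, numeric(1), "dg")
  rep_se <- vapply(rep_stats, `[[`, numeric(1), "se")

  sigma_abar <- if (length(rep_dg) >= 2) replicate_spread(rep_dg) else NA_real_
  mean_se <- mean(rep_se, na.rm = TRUE)
  quality <- if (is.finite(sigma_abar) && is.finite(mean_se) && mean_se > 0)
    sampling_quality(sigma_abar, mean_se)
  else list(ratio = NA_real_, flag = "ok")

  acc_rates <- NULL
  if (!is.null(exch_log)) {
    agg <- stats::aggregate(accepted ~ kind + a + b, data = exch_log,
                            FUN = function(z) c(rate = mean(z),
                                                attempts = length(z)))
    acc_rates <- data.frame(kind = agg$kind, a = agg$a, b = agg$b,
                            rate = agg$accepted[, "rate"],
                            attempts = agg$accepted[, "attempts"])
  }

  structure(
    list(method = label, dg = ti$dg, ti = ti,
         per_window_means = pooled_means, diagnostics = diag,
         replicate_dg = rep_dg, replicate_se = rep_se,
         sigma_abar = sigma_abar, mean_se = mean_se, quality = quality,
         visitation = visit, jump_log = jump_log, exchange_log = exch_log,
         exchange_acceptance = acc_rates, budget = budget,
         records = if (keep_records) records,
         config = config, seed = config$seed),
    class = "run_report")
}

apply_burn_in <- function(records, burn_in) {
  if (burn_in <= 0) return(records)
  keep <- unlist(lapply(split(seq_len(nrow(records)), records$replica),
                        function(idx) idx[-seq_len(ceiling(burn_in *
                                                             length(idx)))]),
                 use.names = FALSE)
  records[sort(keep), , drop = FALSE]
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run report> %s on '%s'\n", x$method, x$config$model$name))
  cat(sprintf("  dG = %.4f kT  (sigma_Abar = %.4f, <SE> = %.4f)\n",
              x$dg, x$sigma_abar, x$mean_se))
  cat(sprintf("  sampling-quality ratio = %.2f [%s]\n",
              x$quality$ratio, x$quality$flag))
  if (!is.null(x$exchange_acceptance)) {
    cat("  exchange acceptance:\n")
    print(x$exchange_acceptance, row.names = FALSE)
  }
  invisible(x)
}

#' Reference fixed-window thermodynamic integration
#'
#' The conventional baseline: one independent walker per window (21 equally
#' spaced windows by default), equal per-window step budgets, no bias and no
#' lambda jumps; optionally Hamiltonian replica exchange between neighbouring
#' windows on the ladder (alternating even/odd pairing) at the exchange
#' interval. Samples are keyed by lambda index, so ladder swaps preserve the
#' per-window streams.
#'
#' @param config a [run_config()]; `n_windows` and the ST-specific settings
#'   are ignored here.
#' @param n_windows number of TI windows (default 21).
#' @param with_exchange attempt neighbour exchanges along the ladder.
#' @return a `run_report` with method label `"21W"` or `"21W+RE"` (or the
#'   window count actually used).
#' @export
run_reference_ti <- function(config, n_windows = 21L, with_exchange = FALSE) {
  stopifnot(inherits(config, "run_config"))
  model <- config$model
  grid <- lambda_grid(n_windows)
  n_w <- grid$n_windows
  seeds <- derive_seeds(config$seed, n_w)
  walkers <- lapply(seq_len(n_w), function(i)
    walker_state(model, lam_index = i, seed = seeds[i]))
  budget <- floor(config$total_steps)
  per_w <- rep(budget %/% n_w, n_w)
  if (budget %% n_w > 0)
    per_w[seq_len(budget %% n_w)] <- per_w[seq_len(budget %% n_w)] + 1

  recs <- list(); exch_log <- list()
  done <- numeric(n_w)
  round_i <- 0L
  while (any(done < per_w)) {
    round_i <- round_i + 1L
    for (r in seq_len(n_w)) {
      chunk <- min(config$exchange_interval, per_w[r] - done[r])
      if (chunk <= 0) next
      out <- propagate(walkers[[r]], model, grid, chunk, beta = config$beta,
                       step_size = config$step_size,
                       record_interval = config$record_interval,
                       sampler = config$sampler)
      walkers[[r]] <- out$state
      if (nrow(out$records)) {
        out$records$replica <- r
        recs[[length(recs) + 1L]] <- out$records
      }
      done[r] <- done[r] + chunk
    }
    if (with_exchange) {
      for (pr in pair_schedule(n_w, round_i, "alternating")) {
        ex <- replica_exchange_attempt(walkers[[pr[1L]]], walkers[[pr[2L]]],
                                       model, grid, config$beta)
        walkers[[pr[1L]]] <- ex$state_m
        walkers[[pr[2L]]] <- ex$state_n
        exch_log[[length(exch_log) + 1L]] <-
          data.frame(kind = "replica_exchange", round = round_i,
                     a = pr[1L], b = pr[2L], delta_u = ex$delta_u,
                     accepted = ex$accepted)
      }
    }
  }
  records <- bind_records(recs)
  finish_report(config, grid, records, visit = NULL, jump_log = NULL,
                exch_log = if (length(exch_log)) do.call(rbind, exch_log),
                label = paste0(n_w, "W", if (with_exchange) "+RE"),
                replicate_mode = "blocks", n_blocks = config$n_replicas,
                budget = list(prescan = 0, main = sum(done),
                              total = sum(done)))
}
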