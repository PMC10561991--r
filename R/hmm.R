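#' Specify a constrained discrete-emission hidden Markov model
#'
#' The sleep-stage model treats binary activity (0 = inactive, 1 = moving)
#' as emissions of four latent stages: deep sleep, light sleep, quiet
#' wake and active wake. Biology enters as structural zeros: a logical
#' "allowed" mask on the transition and emission matrices. Masked entries
#' are exactly zero at initialization and stay exactly zero through
#' training and decoding.
#'
#' @param labels Character vector of state names.
#' @param transition Row-stochastic transition matrix `A`.
#' @param emission Row-stochastic emission matrix `B`, columns = symbols
#'   (inactive, moving).
#' @param initial Initial state distribution.
#' @param allowed_transition,allowed_emission Logical masks; `FALSE`
#'   entries are structural zeros.
#' @return An object of class `hmm_spec`.
#' @export
hmm_spec <- function(labels, transition, emission, initial,
                     allowed_transition = transition > 0,
                     allowed_emission = emission > 0) {
  S <- length(labels)
  stopifnot(
    nrow(transition) == S, ncol(transition) == S,
    nrow(emission) == S,
    length(initial) == S
  )
  check_stochastic <- function(m, name) {
    if (any(abs(rowSums(m) - 1) > 1e-9)) {
      stop(name, " rows must sum to 1", call. = FALSE)
    }
  }
  check_stochastic(transition, "transition")
  check_stochastic(emission, "emission")
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1",
                                         call. = FALSE)
  if (any(transition[!allowed_transition] != 0)) {
    stop("masked transition entries must be exactly 0", call. = FALSE)
  }
  if (any(emission[!allowed_emission] != 0)) {
    stop("masked emission entries must be exactly 0", call. = FALSE)
  }
  dimnames(transition) <- list(labels, labels)
  dimnames(emission) <- list(labels, c("inactive", "moving"))
  names(initial) <- labels
  structure(list(labels = labels, transition = transition,
                 emission = emission, initial = initial,
                 allowed_transition = allowed_transition,
                 allowed_emission = allowed_emission),
            class = "hmm_spec")
}

#' Default four-stage sleep model template
#'
#' States `deep_sleep`, `light_sleep`, `quiet_awake`, `active_awake` on an
#' adjacency chain: each state may persist or step to its neighbour(s),
#' light sleep may additionally jump straight to active wake (abrupt
#' arousal from shallow sleep). Deep sleep cannot wake directly and active
#' wake cannot plunge straight into deep sleep. Both sleep stages are
#' structurally incapable of emitting movement, and active wake always
#' moves; quiet wake is the only stage with a free emission. Pinning the
#' active-wake emission is what identifies the semantic roles of the two
#' wake stages -- with both wake emissions free, the likelihood cannot
#' distinguish "quiet state that sometimes moves" from "active state that
#' sometimes rests", and fitted labels swap. Free probabilities are
#' uniform over the allowed entries of each row. All constraints are
#' overridable by building an [hmm_spec()] by hand.
#'
#' @return An `hmm_spec`.
#' @export
default_hmm_spec <- function() {
  labels <- c("deep_sleep", "light_sleep", "quiet_awake", "active_awake")
  allowed_A <- matrix(FALSE, 4, 4, dimnames = list(labels, labels))
  diag(allowed_A) <- TRUE
  allow <- function(from, to) allowed_A[from, to] <<- TRUE
  allow("deep_sleep", "light_sleep");  allow("light_sleep", "deep_sleep")
  allow("light_sleep", "quiet_awake"); allow("quiet_awake", "light_sleep")
  allow("quiet_awake", "active_awake"); allow("active_awake", "quiet_awake")
  allow("light_sleep", "active_awake")
  A <- allowed_A / rowSums(allowed_A)
  A[!allowed_A] <- 0
  allowed_B <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                        FALSE, FALSE, TRUE, TRUE), 4, 2)
  B <- matrix(c(1, 1, 0.5, 0,
                0, 0, 0.5, 1), 4, 2)
  hmm_spec(labels, A, B, initial = rep(0.25, 4),
           allowed_transition = allowed_A, allowed_emission = allowed_B)
}

#' @export
print.hmm_spec <- function(x, ...) {
  cat("<hmm_spec>", length(x$labels), "states:",
      paste(x$labels, collapse = ", "), "\n")
  cat("transition:\n"); print(round(x$transition, 3))
  cat("emission (inactive, moving):\n"); print(round(x$emission, 3))
  invisible(x)
}

# split each specimen's regular-grid binary series into unbroken
# sequences: NA observations and grid gaps cut
split_sequences <- function(ms, bin_s) {
  stopifnot(all(c("id", "t", "moving") %in% names(ms)))
  obs_ok <- ms$moving[!is.na(ms$moving)]
  if (length(obs_ok) && !all(obs_ok %in% c(0, 1))) {
    stop("observations must be binary {0, 1}", call. = FALSE)
  }
  seqs <- list(); index <- list()
  for (one_id in unique(ms$id)) {
    df <- ms[ms$id == one_id, ]
    df <- df[order(df$t), ]
    gap <- c(FALSE, diff(df$t) > bin_s + 1e-6)
    brk <- cumsum(gap | is.na(df$moving))
    for (piece in split(seq_len(nrow(df)), brk)) {
      piece <- piece[!is.na(df$moving[piece])]
      if (!length(piece)) next
      seqs[[length(seqs) + 1]] <- as.integer(df$moving[piece])
      index[[length(index) + 1]] <- tibble::tibble(id = one_id,
                                                   t = df$t[piece])
    }
  }
  list(obs = seqs, index = index)
}

infer_bin_s <- function(ms) {
  d <- ms |>
    dplyr::summarise(step = stats::median(diff(.data$t)), .by = "id")
  stats::median(d$step, na.rm = TRUE)
}

#' Train the constrained sleep-stage model
#'
#' Constrained Baum--Welch (EM) on the pooled binary activity sequences of
#' all specimens. Structural zeros of the template are preserved at every
#' iteration; within each restart the total log-likelihood is
#' non-decreasing. Several random restarts guard against local optima:
#' restart 1 starts from the template itself, later restarts draw free
#' entries from a seeded Dirichlet. The restart with the highest final
#' log-likelihood wins (ties toward the lowest restart index).
#'
#' @param ms A movement series tibble (`id`, `t`, `moving`); `NA` bins
#'   split sequences.
#' @param spec Template [hmm_spec()] (default [default_hmm_spec()]).
#' @param n_restarts Number of EM restarts (default 5).
#' @param tol Convergence tolerance on the log-likelihood increment.
#' @param max_iter Maximum EM iterations per restart.
#' @param seed Integer seed; the fit is deterministic given it.
#' @param bin_s Grid step; inferred from the data when `NULL`.
#' @return An object of class `behav_hmm`: the fitted `hmm_spec` plus
#'   `$loglik` (best final log-likelihood), `$loglik_trace` (per-restart
#'   iteration traces), `$restart_logliks`, `$best_restart`,
#'   `$degenerate` flag, `$n_obs`, `$bin_s`.
#' @export
train_hmm <- function(ms, spec = default_hmm_spec(), n_restarts = 5,
                      tol = 1e-6, max_iter = 1000, seed = 1, bin_s = NULL) {
  if (is.null(bin_s)) bin_s <- infer_bin_s(ms)
  sq <- split_sequences(ms, bin_s)
  if (!length(sq$obs)) stop("no observations to train on", call. = FALSE)
  all_obs <- unlist(sq$obs)
  degenerate <- length(unique(all_obs)) < 2
  if (degenerate) {
    warning("observations are constant; emission estimates will be degenerate")
  }

  # Restart draws use a sticky-diagonal Dirichlet on transition rows:
  # behavioural stages persist across adjacent bins, so initial guesses
  # with strong self-transitions sit near the relevant likelihood basin,
  # whereas flat draws routinely converge to fast-switching local optima.
  random_init <- function(spec) {
    S <- length(spec$labels)
    rdirich_row <- function(mask, shape) {
      p <- numeric(length(mask))
      g <- stats::rgamma(sum(mask), shape = shape[mask])
      p[mask] <- g / sum(g)
      p
    }
    A <- t(vapply(seq_len(S), function(i) {
      rdirich_row(spec$allowed_transition[i, ],
                  ifelse(seq_len(S) == i, 12, 1))
    }, numeric(S)))
    B <- t(vapply(seq_len(S), function(i) {
      rdirich_row(spec$allowed_emission[i, ],
                  rep(1, ncol(spec$emission)))
    }, numeric(ncol(spec$emission))))
    pi0 <- rdirich_row(rep(TRUE, S), rep(1, S))
    list(A = A, B = B, pi = pi0)
  }

  run_em <- function(A, B, pi0) {
    trace <- numeric(0)
    prev <- -Inf
    for (iter in seq_len(max_iter)) {
      e <- cpp_hmm_estep(sq$obs, A, B, pi0)
      ll <- e$loglik
      if (!is.finite(ll)) return(list(A = A, B = B, pi = pi0,
                                      trace = trace, loglik = -Inf))
      trace <- c(trace, ll)
      if (is.finite(prev) && ll - prev < tol) break
      prev <- ll
      norm_rows <- function(counts, allowed, old) {
        counts[!allowed] <- 0
        rs <- rowSums(counts)
        out <- old
        ok <- rs > 0
        out[ok, ] <- counts[ok, , drop = FALSE] / rs[ok]
        out[!allowed] <- 0
        out
      }
      A <- norm_rows(e$TA, spec$allowed_transition, A)
      B <- norm_rows(e$TB, spec$allowed_emission, B)
      s <- sum(e$Tpi)
      if (s > 0) pi0 <- e$Tpi / s
    }
    list(A = A, B = B, pi = pi0, trace = trace,
         loglik = trace[length(trace)])
  }

  fits <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1)
    init <- if (r == 1) {
      list(A = unname(spec$transition), B = unname(spec$emission),
           pi = unname(spec$initial))
    } else {
      random_init(spec)
    }
    fits[[r]] <- run_em(init$A, init$B, init$pi)
  }
  finals <- vapply(fits, function(f) f$loglik, numeric(1))
  best <- which(finals == max(finals))[1]
  f <- fits[[best]]
  fitted_spec <- hmm_spec(spec$labels, f$A, f$B, f$pi,
                          allowed_transition = spec$allowed_transition,
                          allowed_emission = spec$allowed_emission)
  structure(
    c(fitted_spec,
      list(loglik = f$loglik,
           loglik_trace = lapply(fits, function(x) x$trace),
           restart_logliks = finals, best_restart = best,
           degenerate = degenerate, n_obs = length(all_obs),
           bin_s = bin_s)),
    class = c("behav_hmm", "hmm_spec")
  )
}

#' @export
print.behav_hmm <- function(x, ...) {
  cat("<behav_hmm> fitted", length(x$labels), "state model;",
      "log-likelihood", format(x$loglik), "on", x$n_obs, "bins\n")
  NextMethod()
}

#' @method tidy behav_hmm
#' @export
tidy.behav_hmm <- function(x, ...) {
  A <- x$transition
  tibble::tibble(
    from = rep(rownames(A), times = ncol(A)),
    to = rep(colnames(A), each = nrow(A)),
    probability = as.vector(A),
    allowed = as.vector(x$allowed_transition)
  )
}

#' @method glance behav_hmm
#' @export
glance.behav_hmm <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik,
    n_obs = x$n_obs,
    n_states = length(x$labels),
    best_restart = x$best_restart,
    n_restarts = length(x$restart_logliks),
    degenerate = x$degenerate
  )
}

#' Decode sleep stages from binary activity
#'
#' Viterbi decoding of the most likely stage path per unbroken sequence
#' (ties toward the lowest state index); optionally the forward--backward
#' posterior marginal of each stage is attached per bin.
#'
#' @param fitted A fitted `behav_hmm` (or any [hmm_spec()]).
#' @param ms Movement series tibble (`id`, `t`, `moving`).
#' @param posterior Attach per-state posterior columns (default `TRUE`).
#' @param bin_s Grid step; inferred when `NULL`.
#' @return A tibble (`id`, `t_bin`, `state`, and `p_<state>` columns when
#'   `posterior`).
#' @export
decode_states <- function(fitted, ms, posterior = TRUE, bin_s = NULL) {
  if (is.null(bin_s)) bin_s <- if (!is.null(fitted$bin_s)) fitted$bin_s
                               else infer_bin_s(ms)
  if (any(!ms$moving[!is.na(ms$moving)] %in% c(0, 1))) {
    stop("observations must be binary {0, 1}", call. = FALSE)
  }
  sq <- split_sequences(ms, bin_s)
  safe_log <- function(m) {
    out <- m
    out[m <= 0] <- -Inf
    out[m > 0] <- log(m[m > 0])
    out
  }
  logA <- safe_log(unname(fitted$transition))
  logB <- safe_log(unname(fitted$emission))
  logpi <- safe_log(unname(fitted$initial))
  pieces <- lapply(seq_along(sq$obs), function(k) {
    obs <- sq$obs[[k]]
    path <- cpp_viterbi(obs, logA, logB, logpi) + 1L
    out <- sq$index[[k]]
    out$state <- fitted$labels[path]
    if (posterior) {
      g <- cpp_hmm_posterior(obs, unname(fitted$transition),
                             unname(fitted$emission),
                             unname(fitted$initial))
      colnames(g) <- paste0("p_", fitted$labels)
      out <- dplyr::bind_cols(out, tibble::as_tibble(g))
    }
    out
  })
  out <- dplyr::bind_rows(pieces) |>
    dplyr::rename(t_bin = "t") |>
    dplyr::arrange(.data$id, .data$t_bin)
  out$state <- factor(out$state, levels = fitted$labels)
  out
}

#' Stage occupancy over zeitgeber time
#'
#' Fraction of bins spent in each stage per zeitgeber-time bin (pooled
#' over specimens and days, optionally split by a metadata group).
#' Fractions over the stages sum to 1 in every bin.
#'
#' Two estimators are available. `"viterbi"` counts hard decoded labels --
#' the natural companion to a stage raster. `"posterior"` averages the
#' forward--backward marginals (requires [decode_states()] with
#' `posterior = TRUE`) and is the unbiased choice when the quantity of
#' interest is the occupancy *fraction* itself: the single most likely
#' path systematically over-represents high-probability stages.
#'
#' @param decoded Output of [decode_states()].
#' @param bin_s Zeitgeber bin width, seconds (default 1800).
#' @param meta,group_by Optional grouping.
#' @param lights_on,day_length Zeitgeber reference (seconds).
#' @param weight `"viterbi"` (count decoded labels, default) or
#'   `"posterior"` (average posterior marginals).
#' @return A tibble (`group`, `zt_bin` hours, `state`, `fraction`,
#'   `n_bins`).
#' @export
state_occupancy <- function(decoded, bin_s = 1800, meta = NULL,
                            group_by = NULL, lights_on = 0,
                            day_length = 86400,
                            weight = c("viterbi", "posterior")) {
  weight <- match.arg(weight)
  if (!is.null(group_by)) {
    if (is.null(meta) || !group_by %in% names(meta)) {
      stop("group_by column not found in meta", call. = FALSE)
    }
    decoded <- dplyr::left_join(decoded,
                                dplyr::select(meta, "id",
                                              dplyr::all_of(group_by)),
                                by = "id")
    decoded$group <- as.character(decoded[[group_by]])
  } else {
    decoded$group <- "all"
  }
  bin_h <- bin_s / 3600
  levels_state <- levels(decoded$state)
  decoded <- dplyr::mutate(
    decoded,
    zt = ((.data$t_bin - lights_on) %% day_length) / 3600,
    zt_bin = floor(.data$zt / bin_h) * bin_h
  )
  if (weight == "posterior") {
    p_cols <- paste0("p_", levels_state)
    if (!all(p_cols %in% names(decoded))) {
      stop("posterior weighting needs decode_states(posterior = TRUE)",
           call. = FALSE)
    }
    return(
      decoded |>
        dplyr::summarise(dplyr::across(dplyr::all_of(p_cols), mean),
                         n_bins = dplyr::n(),
                         .by = c("group", "zt_bin")) |>
        tidyr::pivot_longer(dplyr::all_of(p_cols), names_to = "state",
                            values_to = "fraction") |>
        dplyr::mutate(state = factor(sub("^p_", "", .data$state),
                                     levels = levels_state)) |>
        dplyr::select("group", "zt_bin", "state", "fraction", "n_bins") |>
        dplyr::arrange(.data$group, .data$zt_bin, .data$state)
    )
  }
  decoded |>
    dplyr::summarise(n = dplyr::n(), .by = c("group", "zt_bin", "state")) |>
    dplyr::group_by(.data$group, .data$zt_bin) |>
    dplyr::group_modify(function(df, key) {
      total <- sum(df$n)
      full <- tibble::tibble(state = factor(levels_state,
                                            levels = levels_state))
      full <- dplyr::left_join(full, df, by = "state")
      full$n[is.na(full$n)] <- 0
      tibble::tibble(state = full$state, fraction = full$n / total,
                     n_bins = total)
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$group, .data$zt_bin, .data$state)
}

#' Serialize a (fitted) sleep-stage model to JSON
#'
#' @param spec An [hmm_spec()] or fitted `behav_hmm`.
#' @param path Output JSON path.
#' @return `path` (writer) / an `hmm_spec` (reader).
#' @export
write_hmm_json <- function(spec, path) {
  payload <- list(
    labels = spec$labels,
    transition = unname(spec$transition),
    emission = unname(spec$emission),
    initial = unname(spec$initial),
    allowed_transition = unname(spec$allowed_transition),
    allowed_emission = unname(spec$allowed_emission)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_hmm_json
#' @export
read_hmm_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  hmm_spec(p$labels, as.matrix(p$transition), as.matrix(p$emission),
           as.numeric(p$initial),
           allowed_transition = as.matrix(p$allowed_transition),
           allowed_emission = as.matrix(p$allowed_emission))
}
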