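# Two-state ancestry HMM over windowed diagnostic k-mer counts, plus the
# generic log-space Viterbi / forward-backward machinery shared with the
# ancestry-dosage smoother.
#
# Emission model: in state s the number of A-specific occurrences in a window
# is binomial(n_A | n_A + n_B, p_s). Conditioning on the window total makes
# the model invariant to window-to-window density fluctuations. Empty windows
# emit likelihood 1 in both states: uninformative but coordinate-preserving.

# Viterbi in log space; ties broken toward the previous state (fewer segments).
hmm_viterbi <- function(logemis, log_stay, log_switch, log_start) {
  n <- nrow(logemis)
  S <- ncol(logemis)
  if (n == 0) return(integer(0))
  delta <- matrix(-Inf, n, S)
  psi <- matrix(0L, n, S)
  delta[1, ] <- log_start + logemis[1, ]
  for (t in seq_len(n)[-1]) {
    for (s in seq_len(S)) {
      cand <- delta[t - 1, ] + ifelse(seq_len(S) == s, log_stay, log_switch)
      best <- max(cand)
      # prefer no switch on ties
      prev <- if (cand[s] >= best) s else which.max(cand)
      psi[t, s] <- prev
      delta[t, s] <- cand[prev] + logemis[t, s]
    }
  }
  path <- integer(n)
  last <- delta[n, ]
  path[n] <- which(last == max(last))[1]
  for (t in rev(seq_len(n - 1))) path[t] <- psi[t + 1, path[t + 1]]
  path
}

# Scaled forward-backward; returns posteriors and the data log-likelihood.
hmm_forward_backward <- function(logemis, log_stay, log_switch, log_start) {
  n <- nrow(logemis)
  S <- ncol(logemis)
  emis <- exp(logemis - apply(logemis, 1, max))
  scale_emis <- apply(logemis, 1, max)
  trans <- matrix(exp(log_switch), S, S)
  diag(trans) <- exp(log_stay)
  alpha <- matrix(0, n, S)
  cvec <- numeric(n)
  a <- exp(log_start) * emis[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in seq_len(n)[-1]) {
    a <- (alpha[t - 1, ] %*% trans)[1, ] * emis[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, n, S)
  beta[n, ] <- 1
  if (n > 1) {
    for (t in rev(seq_len(n - 1))) {
      b <- trans %*% (emis[t + 1, ] * beta[t + 1, ])
      beta[t, ] <- b[, 1] / cvec[t + 1]
    }
  }
  post <- alpha * beta
  post <- post / rowSums(post)
  list(posterior = post, loglik = sum(log(cvec)) + sum(scale_emis))
}

#' Estimate HMM emission parameters from labeled tracks
#'
#' Pools windows of chromosomes assigned to each subgenome -- trimmed of
#' their distal 25% to keep exchanged tails out of the estimate -- and sets
#' `p_A` (probability that an occurrence is A-specific in state A) to the
#' pooled fraction `n_A / (n_A + n_B)`, likewise `p_B`. Optionally refines
#' both by Baum-Welch EM.
#'
#' @param track Density track from [density_track()].
#' @param partition A `subgenome_partition`.
#' @param trim_frac Distal fraction of each chromosome excluded from the
#'   pooled estimate (default 0.25).
#' @param switch_prob Per-boundary state-switch probability (default 1e-3).
#' @param em Run EM refinement.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return An `hmm_params` list: `p_A`, `p_B`, `switch_prob`, `start_probs`.
#' @export
estimate_emissions <- function(track, partition, trim_frac = 0.25,
                               switch_prob = 1e-3, em = FALSE,
                               max_iter = 50, tol = 1e-6) {
  if (sum(track$n_A + track$n_B) == 0) {
    stop_degenerate("All-zero density track: emissions cannot be estimated.")
  }
  lab <- partition$assignment[track$chrom]
  if (!any(lab == "A", na.rm = TRUE) || !any(lab == "B", na.rm = TRUE)) {
    stop_input("Need at least one chromosome per subgenome.")
  }
  trimmed <- dplyr::bind_rows(lapply(split(track, track$chrom), function(tr) {
    n <- nrow(tr)
    tr[tr$window < ceiling((1 - trim_frac) * n), , drop = FALSE]
  }))
  lab_t <- partition$assignment[trimmed$chrom]
  pool <- function(which_lab) {
    sub <- trimmed[lab_t == which_lab & !is.na(lab_t), ]
    tot <- sum(sub$n_A + sub$n_B)
    if (tot == 0) stop_degenerate("All-zero track for one subgenome.")
    sum(sub$n_A) / tot
  }
  clamp <- function(p) min(max(p, 1e-6), 1 - 1e-6)
  p_a <- clamp(pool("A"))
  p_b <- clamp(pool("B"))
  params <- new_hmm_params(p_a, p_b, switch_prob)

  if (em) {
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      num_a <- den_a <- num_b <- den_b <- 0
      ll <- 0
      for (tr in split(track, track$chrom)) {
        le <- emission_loglik(tr$n_A, tr$n_B, params)
        fb <- hmm_forward_backward(le, log(1 - switch_prob), log(switch_prob),
                                   log(params$start_probs))
        tot <- tr$n_A + tr$n_B
        num_a <- num_a + sum(fb$posterior[, 1] * tr$n_A)
        den_a <- den_a + sum(fb$posterior[, 1] * tot)
        num_b <- num_b + sum(fb$posterior[, 2] * tr$n_A)
        den_b <- den_b + sum(fb$posterior[, 2] * tot)
        ll <- ll + fb$loglik
      }
      params$p_A <- clamp(num_a / den_a)
      params$p_B <- clamp(num_b / den_b)
      if (abs(ll - ll_old) < tol) break
      ll_old <- ll
    }
    if (params$p_A < params$p_B) {  # keep state 1 = A-rich orientation
      params[c("p_A", "p_B")] <- params[c("p_B", "p_A")]
    }
  }
  params
}

new_hmm_params <- function(p_A, p_B, switch_prob = 1e-3,
                           start_probs = c(0.5, 0.5)) {
  if (!(switch_prob > 0 && switch_prob < 0.5)) {
    stop_input("`switch_prob` must lie in (0, 0.5).")
  }
  if (!(p_B < p_A)) stop_input("Emission parameters must satisfy p_B < p_A.")
  structure(list(p_A = p_A, p_B = p_B, switch_prob = switch_prob,
                 start_probs = start_probs), class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("<hmm_params> p_A = %.4f, p_B = %.4f, switch_prob = %g\n",
              x$p_A, x$p_B, x$switch_prob))
  invisible(x)
}

emission_loglik <- function(n_a, n_b, params) {
  tot <- n_a + n_b
  le <- cbind(dbinom(n_a, tot, params$p_A, log = TRUE),
              dbinom(n_a, tot, params$p_B, log = TRUE))
  le[tot == 0, ] <- 0  # empty windows are uninformative
  le
}

#' Decode window ancestry with the two-state HMM
#'
#' Computes the Viterbi path and forward-backward posteriors per chromosome.
#'
#' @param track Density track from [density_track()].
#' @param params An `hmm_params` object (see [estimate_emissions()]).
#' @return The track tibble with `state` ("A"/"B"), `posterior_A`,
#'   `posterior_B` columns; attribute `loglik` holds the total data
#'   log-likelihood.
#' @export
decode_ancestry <- function(track, params) {
  ls <- log(1 - params$switch_prob)
  lw <- log(params$switch_prob)
  l0 <- log(params$start_probs)
  out <- lapply(split(track, track$chrom), function(tr) {
    tr <- tr[order(tr$window), , drop = FALSE]
    le <- emission_loglik(tr$n_A, tr$n_B, params)
    path <- hmm_viterbi(le, ls, lw, l0)
    fb <- hmm_forward_backward(le, ls, lw, l0)
    tr$state <- c("A", "B")[path]
    tr$posterior_A <- fb$posterior[, 1]
    tr$posterior_B <- fb$posterior[, 2]
    attr(tr, "loglik") <- fb$loglik
    tr
  })
  res <- dplyr::bind_rows(out)
  attr(res, "loglik") <- sum(vapply(out, attr, numeric(1), "loglik"))
  res
}

#' Segment a decoded ancestry path
#'
#' Collapses the Viterbi path into maximal constant-state runs; runs shorter
#' than `min_windows` are absorbed into the flanking run with the higher
#' adjacent posterior, so single-window noise does not fragment segments.
#' Run length is counted in informative windows (`n_A + n_B > 0`): empty
#' windows carry no evidence, so a blip supported by one or two stray
#' occurrences cannot reach the minimum by spanning empty gaps. Among
#' several short runs the least-supported one (lowest mean posterior for its
#' own state) is merged first, so a weakly supported blip never overrides a
#' strongly supported neighbor.
#'
#' @param decoded Output of [decode_ancestry()].
#' @param min_windows Minimum run length retained as its own segment.
#' @return A tibble of segments: `chrom`, `start`, `end` (bp, 0-based
#'   half-open, tiling each chromosome), `state`, `mean_posterior` (the
#'   occurrence-weighted mean posterior of the segment's state, so windows
#'   carrying no evidence do not dilute support), `n_windows`. Adjacent
#'   segments differ in state.
#' @export
segment_ancestry <- function(decoded, min_windows = 3) {
  parts <- lapply(split(decoded, decoded$chrom), function(tr) {
    tr <- tr[order(tr$window), , drop = FALSE]
    state <- tr$state
    informative <- (tr$n_A + tr$n_B) > 0
    post_own <- ifelse(state == "A", tr$posterior_A, tr$posterior_B)
    repeat {
      r <- rle(state)
      if (length(r$lengths) <= 1) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      info_len <- vapply(seq_along(starts), function(j) {
        sum(informative[starts[j]:ends[j]])
      }, numeric(1))
      short <- which(info_len < min_windows)
      if (length(short) == 0) break
      run_post <- function(j) mean(post_own[starts[j]:ends[j]])
      i <- short[which.min(vapply(short, run_post, numeric(1)))]
      nb <- c(if (i > 1) i - 1, if (i < length(r$lengths)) i + 1)
      takeover <- nb[which.max(vapply(nb, run_post, numeric(1)))]
      state[starts[i]:ends[i]] <- r$values[takeover]
      post_own <- ifelse(state == "A", tr$posterior_A, tr$posterior_B)
    }
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    tibble(chrom = tr$chrom[1],
           start = tr$start[starts],
           end = tr$end[ends],
           state = r$values,
           mean_posterior = vapply(seq_along(starts), function(j) {
             p <- if (r$values[j] == "A") tr$posterior_A else tr$posterior_B
             idx <- starts[j]:ends[j]
             w <- (tr$n_A + tr$n_B)[idx]
             if (sum(w) > 0) sum(p[idx] * w) / sum(w) else mean(p[idx])
           }, numeric(1)),
           n_windows = r$lengths)
  })
  dplyr::bind_rows(parts)
}

#' Call homeologous exchanges from ancestry segments
#'
#' A segment whose state differs from its chromosome's bulk subgenome
#' assignment is an exchange call. A call is flagged reciprocal when the
#' homeolog partner carries a complementary opposite-state segment with at
#' least 50% reciprocal coordinate overlap; calls touching a chromosome end
#' are annotated distal. Segments with mean posterior below `min_posterior`
#' are not called: isolated stray k-mer coincidences in sparse regions
#' produce weakly supported blips (posterior well under 0.9), whereas true
#' exchanged segments decode at posterior ~1.
#'
#' @param segments Output of [segment_ancestry()].
#' @param partition A `subgenome_partition`.
#' @param homeolog_map Homeolog pairing tibble.
#' @param min_posterior Call-confidence floor on the segment mean posterior.
#' @return A tibble of calls: `chrom`, `start`, `end`, `state`, `bulk`,
#'   `distal`, `reciprocal`, `partner`, `mean_posterior`. Zero rows when no
#'   segment deviates from its chromosome's bulk assignment.
#' @export
call_exchanges <- function(segments, partition, homeolog_map,
                           min_posterior = 0.9) {
  chrom_len <- vapply(split(segments$end, segments$chrom), max, numeric(1))
  partner_of <- c(setNames(homeolog_map$member_2, homeolog_map$member_1),
                  setNames(homeolog_map$member_1, homeolog_map$member_2))
  bulk <- partition$assignment
  seg <- segments
  seg$bulk <- bulk[seg$chrom]
  calls <- seg[!is.na(seg$bulk) & seg$state != seg$bulk &
                 seg$mean_posterior >= min_posterior, , drop = FALSE]
  if (nrow(calls) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  state = character(), bulk = character(), distal = logical(),
                  reciprocal = logical(), partner = character(),
                  mean_posterior = numeric()))
  }
  calls$distal <- calls$start == 0 | calls$end >= chrom_len[calls$chrom]
  calls$partner <- unname(partner_of[calls$chrom])
  calls$reciprocal <- vapply(seq_len(nrow(calls)), function(i) {
    p <- calls$partner[[i]]
    if (is.na(p) || !p %in% seg$chrom) {
      warn(sprintf("No segmentation for partner of %s; partial call.",
                   calls$chrom[[i]]))
      return(NA)
    }
    pc <- seg[seg$chrom == p & seg$state != seg$bulk, , drop = FALSE]
    if (nrow(pc) == 0) return(FALSE)
    ov <- pmax(0, pmin(calls$end[[i]], pc$end) - pmax(calls$start[[i]], pc$start))
    any(ov / (calls$end[[i]] - calls$start[[i]]) >= 0.5 &
          ov / (pc$end - pc$start) >= 0.5)
  }, logical(1))
  as_tibble(calls[, c("chrom", "start", "end", "state", "bulk", "distal",
                      "reciprocal", "partner", "mean_posterior")])
}
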