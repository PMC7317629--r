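# Shared fixture builders and independent oracles. Oracles here are written
# as direct transcriptions of the defining formulas (loops, enumeration) so
# they stay independent of the package's implementation paths.

make_deficit_matrix <- function(values,
                                window = as.Date(c("2005-01-01", "2005-12-31"))) {
  structure(list(values = values, window = window), class = "deficit_matrix")
}

ascertain_window <- function(cohort) {
  c(cohort$config$baseline_start, cohort$subjects$followup_start[1] - 1)
}

# Brute-force per-subject deficit tally: literal restatement of the
# >=3-outpatient / >=1-inpatient rule with nested loops.
oracle_deficits <- function(claims, catalog, window, subject_ids) {
  cl <- unique(claims[, c("subject_id", "service_date", "setting", "icd9")])
  cl <- cl[cl$service_date >= window[1] & cl$service_date <= window[2], ]
  norm <- function(z) toupper(gsub("[. ]", "", z))
  out <- matrix(0L, length(subject_ids), nrow(catalog),
                dimnames = list(subject_ids, catalog$condition_id))
  for (s in subject_ids) {
    mine <- cl[cl$subject_id == s, ]
    for (k in seq_len(nrow(catalog))) {
      prefixes <- norm(strsplit(catalog$icd9_prefixes[k], ";")[[1]])
      n_out <- 0L; n_in <- 0L
      for (i in seq_len(nrow(mine))) {
        code <- norm(mine$icd9[i])
        if (any(startsWith(code, prefixes))) {
          if (mine$setting[i] == "outpatient") n_out <- n_out + 1L
          else n_in <- n_in + 1L
        }
      }
      if (n_out >= 3L || n_in >= 1L) out[s, k] <- 1L
    }
  }
  out
}

# Product-limit estimator computed directly from its definition.
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  surv <- numeric(length(tt))
  s <- 1
  for (i in seq_along(tt)) {
    at_risk <- sum(time >= tt[i])
    d <- sum(time == tt[i] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  data.frame(time = tt, surv = surv)
}

# Log-rank statistic as the per-event-time hypergeometric sum.
oracle_logrank <- function(time, event, group) {
  group <- as.factor(group)
  g <- levels(group)
  tt <- sort(unique(time[event == 1]))
  O <- E <- stats::setNames(numeric(length(g)), g)
  Vg <- matrix(0, length(g), length(g), dimnames = list(g, g))
  for (ti in tt) {
    n <- sum(time >= ti)
    d <- sum(time == ti & event == 1)
    for (a in g) {
      na <- sum(time >= ti & group == a)
      O[a] <- O[a] + sum(time == ti & event == 1 & group == a)
      E[a] <- E[a] + d * na / n
    }
    if (n > 1) {
      for (a in g) for (b in g) {
        na <- sum(time >= ti & group == a)
        nb <- sum(time >= ti & group == b)
        Vg[a, b] <- Vg[a, b] +
          d * (n - d) / (n - 1) * (na * ((a == b) * n - nb)) / n^2
      }
    }
  }
  om <- (O - E)[-1]
  chisq <- drop(t(om) %*% solve(Vg[-1, -1, drop = FALSE]) %*% om)
  list(chisq = chisq, O = O, E = E)
}

# Cox partial log-likelihood for a single binary covariate, no ties.
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Harrell's C by O(n^2) pairwise counting.
oracle_concordance <- function(time, event, risk) {
  conc <- disc <- ties <- 0
  n <- length(time)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    # pair comparable when the earlier time is an event
    if (time[i] == time[j] && event[i] == event[j]) next
    first <- if (time[i] < time[j]) i else j
    other <- if (first == i) j else i
    if (time[i] == time[j]) first <- if (event[i] == 1) i else j
    if (event[first] != 1) next
    if (risk[first] > risk[other]) conc <- conc + 1
    else if (risk[first] < risk[other]) disc <- disc + 1
    else ties <- ties + 1
  }
  (conc + 0.5 * ties) / (conc + disc + ties)
}

# Independent cut-point enumeration: for each ordered triple build KM curves
# with survfit directly, apply feasibility, max-min distance then min-max
# coverage, lexicographic final tie-break. When nothing is feasible, the
# winner is the best infeasible candidate by worst-time distance (the same
# contract the search reports).
oracle_search <- function(triples, scores, time, event, grid_times,
                          min_group_size) {
  best <- NULL
  best_infeas <- NULL
  for (r in seq_len(nrow(triples))) {
    cc <- triples[r, ]
    lab <- cut(scores, c(-Inf, cc, Inf), right = FALSE,
               labels = c("fit", "mild", "moderate", "severe"))
    if (any(table(lab) < min_group_size)) next
    fit <- survival::survfit(survival::Surv(time, event) ~ lab,
                             conf.type = "log-log")
    sm <- summary(fit, times = grid_times, extend = TRUE)
    strat <- sub("^lab=", "", as.character(sm$strata))
    S <- sapply(levels(lab), function(g) sm$surv[strat == g])
    L <- sapply(levels(lab), function(g) sm$lower[strat == g])
    U <- sapply(levels(lab), function(g) sm$upper[strat == g])
    L[is.na(L)] <- S[is.na(L)]; U[is.na(U)] <- S[is.na(U)]
    gaps <- S[, 1:3] - S[, 2:4]
    D <- apply(gaps, 1, min)
    Cv <- rowSums(U - L) / (S[, 1] - S[, 4])
    cand <- list(cc = cc, minD = min(D),
                 maxC = if (any(S[, 1] <= S[, 4])) Inf else max(Cv))
    if (!all(gaps > 0) || !all(L[, 1:3] > U[, 2:4])) {
      if (is.null(best_infeas) || cand$minD > best_infeas$minD)
        best_infeas <- cand
      next
    }
    lex_smaller <- function(a, b) {
      d <- which(a != b)
      length(d) > 0 && a[d[1]] < b[d[1]]
    }
    if (is.null(best) ||
        cand$minD > best$minD ||
        (cand$minD == best$minD && cand$maxC < best$maxC) ||
        (cand$minD == best$minD && cand$maxC == best$maxC &&
           lex_smaller(cand$cc, best$cc))) {
      best <- cand
    }
  }
  if (!is.null(best)) c(best, list(feasible = TRUE))
  else if (!is.null(best_infeas)) c(best_infeas, list(feasible = FALSE))
  else NULL
}
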