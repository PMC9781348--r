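# Independent brute-force oracles the fast implementations are checked
# against. These deliberately share no code with the package internals:
# plain double loops and linear scans only.

# all-pairs chain builder: for every peak, test suppression by scanning for
# a predecessor at -delta, then grow the chain one k at a time by scanning
# every peak for the closest match within tol (ties -> lowest m/z).
brute_force_series <- function(mz, delta, tol, k_max) {
  out <- list()
  for (i in seq_along(mz)) {
    if (any(abs(mz - (mz[i] - delta)) <= tol)) next  # not the lowest base
    members <- i
    for (k in seq_len(k_max)) {
      d <- abs(mz - (mz[i] + k * delta))
      best <- which.min(d)  # ties resolve to the lowest m/z
      if (d[best] <= tol) members <- c(members, best) else break
    }
    if (length(members) >= 2L) {
      out[[length(out) + 1L]] <- list(base = i, members = members)
    }
  }
  out
}

# naive triple-loop CHO enumeration for one neutral mass
brute_force_enumerate <- function(neutral_mass, cfg) {
  mH <- 1.0078250319
  mC <- 12
  mO <- 15.9949146221
  hits <- list()
  for (cc in 1:cfg$c_max) {
    for (oo in 0:cfg$o_max) {
      for (hh in 0:cfg$h_max) {
        mass <- mC * cc + mH * hh + mO * oo
        err <- (mass - neutral_mass) / neutral_mass * 1e6
        if (abs(err) > cfg$tol_ppm) next
        if (hh / cc < cfg$hc_range[1] || hh / cc > cfg$hc_range[2]) next
        if (oo / cc > cfg$oc_max) next
        if (cfg$require_integer_dbe && hh %% 2 != 0) next
        if (cc - hh / 2 + 1 < 0) next
        if (hh > 2 * cc + 2) next
        hits[[length(hits) + 1L]] <- c(c = cc, h = hh, o = oo, err = err)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(c = integer(), h = integer(), o = integer(),
                      err = numeric()))
  }
  df <- as.data.frame(do.call(rbind, hits))
  df[order(abs(df$err), df$o, df$c), , drop = FALSE]
}

# brute-force optimal one-to-one matching by total |dmz| on tiny inputs
# (enumerates all assignments)
brute_force_match_count <- function(mza, mzb, tol) {
  pairs <- expand.grid(a = seq_along(mza), b = seq_along(mzb))
  pairs <- pairs[abs(mza[pairs$a] - mzb[pairs$b]) <= tol, , drop = FALSE]
  best <- 0L
  n <- nrow(pairs)
  if (!n) return(0L)
  for (mask in 0:(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    if (anyDuplicated(pairs$a[sel]) || anyDuplicated(pairs$b[sel])) next
    best <- max(best, length(sel))
  }
  best
}

# minimal hand-built component-records table for merge/filter tests
make_records <- function(formulas, routes = "parenteral", n_support = 3L,
                         in_labeled_ref = TRUE, n_exchangeable = 2L) {
  f <- derepms::parse_formula(formulas)
  recs <- data.frame(
    formula = formulas, c = f$c, h = f$h, o = f$o, d = 0L, br = 0L,
    n_support = rep_len(n_support, length(formulas)),
    in_labeled_ref = rep_len(in_labeled_ref, length(formulas)),
    n_exchangeable = rep_len(n_exchangeable, length(formulas)),
    base_mz = derepms::mz_from_formula(f)
  )
  recs$routes <- rep(list(routes), length(formulas))
  recs$evidence <- rep(list(character()), length(formulas))
  class(recs) <- c("component_records", "data.frame")
  recs
}
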