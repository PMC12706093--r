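#' Exact test of independence for an r x c contingency table
#'
#' Two-tailed Fisher's exact test. 2 x 2 tables are evaluated by direct
#' hypergeometric enumeration with the point-probability rule (the p value
#' sums the probabilities of all tables, with the observed margins, whose
#' probability does not exceed that of the observed table). Larger tables
#' are evaluated by complete enumeration of all tables with the observed
#' margins when their number does not exceed `max_enumerate`, and otherwise
#' by Monte Carlo sampling of margin-conditioned tables ([stats::r2dtable()])
#' with a fixed seed.
#'
#' Rows or columns with a zero margin carry no information and are dropped
#' with a warning.
#'
#' @param table integer matrix of non-negative counts, at least 2 x 2.
#' @param max_enumerate enumeration budget for r x c tables (default 1e6).
#' @param n_samples Monte Carlo sample count (default 1e5).
#' @param seed Monte Carlo seed (default 1).
#' @return a `fisher_result` list: `p_value`, `method` ("enumeration" or
#'   "monte_carlo"), `n_samples` and `seed` (NA unless Monte Carlo).
#' @export
fisher_exact_rc <- function(table, max_enumerate = 1e6, n_samples = 1e5,
                            seed = 1L) {
  tb <- as.matrix(table)
  if (any(tb < 0) || any(tb != round(tb))) abort("table must hold counts")
  storage.mode(tb) <- "integer"
  rs <- rowSums(tb); cs <- colSums(tb)
  if (any(rs == 0) || any(cs == 0)) {
    warn("dropping zero-margin rows/columns")
    tb <- tb[rs > 0, cs > 0, drop = FALSE]
    rs <- rowSums(tb); cs <- colSums(tb)
  }
  if (nrow(tb) < 2 || ncol(tb) < 2)
    abort("table must be at least 2 x 2 after dropping zero margins")

  if (nrow(tb) == 2 && ncol(tb) == 2) {
    p <- .fisher_2x2(tb)
    return(structure(list(p_value = p, method = "enumeration",
                          n_samples = NA_integer_, seed = NA_integer_),
                     class = "fisher_result"))
  }

  n_tables <- .count_margin_tables(rs, cs)
  lp_obs <- .log_table_prob(tb, rs, cs)
  tol <- 1e-7
  if (!is.na(n_tables) && n_tables <= max_enumerate) {
    p <- .enumerate_margin_tables(rs, cs, lp_obs, tol)
    structure(list(p_value = min(p, 1), method = "enumeration",
                   n_samples = NA_integer_, seed = NA_integer_),
              class = "fisher_result")
  } else {
    set.seed(seed)
    sims <- r2dtable(n_samples, rs, cs)
    lps <- vapply(sims, .log_table_prob, 0, rs = rs, cs = cs)
    p <- mean(lps <= lp_obs + tol)
    structure(list(p_value = p, method = "monte_carlo",
                   n_samples = as.integer(n_samples),
                   seed = as.integer(seed)),
              class = "fisher_result")
  }
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("<fisher_result> p =", format(x$p_value), "(", x$method, ")\n")
  invisible(x)
}

# two-tailed 2x2 exact test, point-probability rule
.fisher_2x2 <- function(tb) {
  m <- sum(tb[1, ]); n <- sum(tb[2, ]); k <- sum(tb[, 1])
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(tb[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# log multivariate hypergeometric probability of a margin-fixed table
.log_table_prob <- function(tb, rs, cs) {
  sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(rs)) - sum(lfactorial(tb))
}

# number of non-negative integer tables with the given margins (DP over
# rows on the distribution of partial column sums); NA if astronomically
# many (counts use doubles)
.count_margin_tables <- function(rs, cs) {
  # represent the set of reachable partial column-sum vectors; count paths
  states <- new.env(hash = TRUE, parent = emptyenv())
  assign(paste(rep(0L, length(cs)), collapse = ","), 1,
         envir = states)
  for (i in seq_along(rs)) {
    nxt <- new.env(hash = TRUE, parent = emptyenv())
    remaining <- if (i < length(rs)) sum(rs[(i + 1):length(rs)]) else 0
    for (key in ls(states)) {
      cur <- as.integer(strsplit(key, ",")[[1]])
      cnt <- get(key, envir = states)
      for (row in .compositions(rs[i], cs - cur)) {
        new <- cur + row
        if (any(cs - new > remaining)) next
        nk <- paste(new, collapse = ",")
        prev <- if (exists(nk, envir = nxt)) get(nk, envir = nxt) else 0
        assign(nk, prev + cnt, envir = nxt)
        if (prev + cnt > 1e15) return(NA_real_)
      }
      if (length(ls(nxt)) > 2e5) return(NA_real_)
    }
    states <- nxt
  }
  total <- 0
  for (key in ls(states)) total <- total + get(key, envir = states)
  total
}

# all compositions of n into length(caps) parts with part j <= caps[j]
.compositions <- function(n, caps) {
  k <- length(caps)
  out <- list()
  rec <- function(prefix, rem, j) {
    if (j == k) {
      if (rem <= caps[j]) out[[length(out) + 1L]] <<- c(prefix, rem)
      return(invisible())
    }
    hi <- min(rem, caps[j])
    lo <- max(0L, rem - sum(caps[(j + 1):k]))
    for (v in lo:hi) if (hi >= lo) rec(c(prefix, v), rem - v, j + 1L)
  }
  rec(integer(0), n, 1L)
  out
}

# complete enumeration p value: sum of probabilities of margin tables whose
# probability is <= that of the observed table
.enumerate_margin_tables <- function(rs, cs, lp_obs, tol) {
  lconst <- sum(lfactorial(rs)) + sum(lfactorial(cs)) -
    lfactorial(sum(rs))
  p <- 0
  nr <- length(rs)
  rec <- function(rows_done, cs_left, lfact_acc) {
    i <- rows_done + 1L
    if (i == nr) {
      lp <- lconst - (lfact_acc + sum(lfactorial(cs_left)))
      if (lp <= lp_obs + tol) p <<- p + exp(lp)
      return(invisible())
    }
    for (row in .compositions(rs[i], cs_left)) {
      remaining <- sum(rs[(i + 1):nr])
      if (any(cs_left - row > remaining)) next
      rec(i, cs_left - row, lfact_acc + sum(lfactorial(row)))
    }
  }
  rec(0L, cs, 0)
  p
}
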