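# Independent brute-force oracles used across test files. These stay naive
# on purpose: they enumerate rather than reuse any package code path.

# AUC by explicit pair enumeration: P(case score > control score) + half ties
auc_enumerate <- function(scores, labels) {
  cs <- scores[labels == "case"]
  ct <- scores[labels == "control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# Unnormalized betweenness by exhaustive shortest-path enumeration on a
# small undirected graph given as an edge matrix of node names.
betweenness_enumerate <- function(edges) {
  nodes <- sort(unique(c(edges[, 1], edges[, 2])))
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    adj[edges[i, 1], edges[i, 2]] <- TRUE
    adj[edges[i, 2], edges[i, 1]] <- TRUE
  }
  # all shortest paths between a pair by breadth-limited DFS
  all_paths <- function(s, t) {
    best <- Inf
    found <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (length(path) - 1 > best) return()
      if (last == t) {
        d <- length(path) - 1
        if (d < best) {
          best <<- d
          found <<- list(path)
        } else if (d == best) {
          found[[length(found) + 1]] <<- path
        }
        return()
      }
      for (nb in nodes[adj[last, ]])
        if (!nb %in% path) walk(c(path, nb))
    }
    walk(s)
    found
  }
  btw <- setNames(numeric(n), nodes)
  for (i in seq_len(n - 1)) for (j in seq.int(i + 1, n)) {
    paths <- all_paths(nodes[i], nodes[j])
    if (length(paths) == 0) next
    for (p in paths) {
      inner <- setdiff(p, c(nodes[i], nodes[j]))
      for (v in inner) btw[v] <- btw[v] + 1 / length(paths)
    }
  }
  btw
}

# BH step-up by the textbook definition: sort, multiply by n/rank, take the
# cumulative minimum from the largest p down, cap at 1, restore input order.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# Cox partial log-likelihood (Breslow ties) for a single covariate, and its
# maximizer by dense grid search — independent of survival::coxph.
cox_partial_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    d <- which(time == t & event == 1)
    risk <- which(time >= t)
    ll <- ll + sum(beta * x[d]) -
      length(d) * log(sum(exp(beta * x[risk])))
  }
  ll
}

cox_grid_mle <- function(x, time, event, lo = -3, hi = 3, step = 1e-3) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, cox_partial_loglik, 0.0, x = x, time = time,
               event = event)
  grid[which.max(ll)]
}

# Kaplan-Meier by direct product over event times
km_hand <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    d <- sum(time == t & event == 1)
    n_risk <- sum(time >= t)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  list(time = ev_times, surv = out)
}

# small deterministic expression dataset for unit tests
toy_dataset <- function(n_genes = 20, n_case = 4, n_control = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n_case + n_control), mean = 7),
              nrow = n_genes,
              dimnames = list(sprintf("G%03d", seq_len(n_genes)),
                              sprintf("S%02d", seq_len(n_case + n_control))))
  expression_dataset(m, rep(c("case", "control"), c(n_case, n_control)),
                     "toy")
}

# shared small study bundle: written once per test run, reused across files
pipeline_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "reporternet-pipeline-fixture")
      b <- generate_bundle(n_genes = 300, n_tf = 25, n_receptor = 25,
                           n_active_tf = 3, n_active_receptor = 3,
                           val_n_case = 60, val_n_control = 25,
                           n_prognostic = 3, seed = 42L)
      write_bundle(b, dir)
      cache <<- list(dir = dir, bundle = b)
    }
    cache
  }
})
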