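#' Solve a square linear sum assignment problem
#'
#' Jonker–Volgenant shortest-augmenting-path algorithm (O(n^3)), minimizing
#' the total cost of a perfect matching on a square cost matrix.  Used by the
#' tracker to find the globally best frame-to-frame pairing; the minimum cost
#' corresponds to the maximum overall assignment probability when the costs
#' are inverse displacement likelihoods.
#'
#' @param cost square numeric matrix of finite costs.
#' @return integer vector `m` with `m[i]` the column assigned to row `i`.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || nrow(cost) != ncol(cost))
    stop("cost must be a square matrix")
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  if (any(!is.finite(cost))) stop("cost entries must be finite")
  u <- numeric(n)
  v <- numeric(n + 1L)          # v[n + 1] is the virtual start column
  p <- integer(n + 1L)          # p[j]: row currently assigned to column j
  cols <- seq_len(n)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n)
    way <- integer(n)
    used <- logical(n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[cols])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      j1 <- free[which.min(minv[free])]
      delta <- minv[j1]
      usedc <- which(used)
      ur <- p[usedc]            # all used columns hold an assigned row
      u[ur] <- u[ur] + delta
      v[usedc] <- v[usedc] - delta
      minv[!used[cols]] <- minv[!used[cols]] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  match <- integer(n)
  match[p[cols]] <- cols
  match
}

# exhaustive minimum over all injections of rows into columns; oracle-grade,
# only for small instances
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  k <- min(n, m)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; best_assign <- NULL
  if (n <= m) {
    for (p in perms(seq_len(m))) {
      sel <- p[seq_len(n)]
      tot <- sum(cost[cbind(seq_len(n), sel)])
      if (tot < best) { best <- tot; best_assign <- sel }
    }
  } else {
    for (p in perms(seq_len(n))) {
      sel <- p[seq_len(m)]
      tot <- sum(cost[cbind(sel, seq_len(m))])
      if (tot < best) {
        best <- tot
        best_assign <- integer(n)
        best_assign[sel] <- seq_len(m)
      }
    }
  }
  list(cost = best, assignment = best_assign)
}
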