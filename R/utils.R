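#' @importFrom stats aov coef cor fft kmeans prcomp predict pchisq pt quantile
#'   rnorm rpois runif sd setNames t.test chisq.test
#' @importFrom utils head read.csv write.csv
NULL

# stop() with a consistent prefix so callers can match on message content
abort_config <- function(...) stop("invalid config: ", ..., call. = FALSE)

check_number <- function(x, name, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_config(name, " must be a single finite number")
  if (strict_min && x <= min) abort_config(name, " must be > ", min)
  if (!strict_min && x < min) abort_config(name, " must be >= ", min)
  x
}

# Solve the linear assignment problem (minimise total cost) for an n x m cost
# matrix with n <= m. Returns an integer vector of length n: assigned column
# per row. Shortest-augmenting-path (Jonker-Volgenant style) in O(n^2 m).
solve_assignment <- function(cost) {
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L || m == 0L) return(integer(0))
  stopifnot(n <= m)
  INF <- .Machine$double.xmax / 4
  # index 1 of length-(m+1) vectors is the virtual column; real column j is j+1
  v <- numeric(m + 1)
  u <- numeric(n + 1)
  p <- integer(m + 1)           # p[j+1] = row matched to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- INF
      j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assignment[p[j + 1]] <- j
  assignment
}
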