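# Independent brute-force maximum-likelihood oracle for the 4-parameter
# stay logistic regression: dense grid search then Nelder-Mead polish.
# Shares no code with the package's Newton solver.
oracle_logit <- function(rows, ridge = 0) {
  X <- cbind(1, rows$prev_reward, rows$prev_transition,
             rows$prev_reward * rows$prev_transition)
  y <- rows$stay
  nll <- function(b) {
    eta <- drop(X %*% b)
    -sum(y * eta - log1p(exp(eta))) + ridge * sum(b^2)
  }
  grid1 <- seq(-3, 3, by = 0.5)
  grid <- as.matrix(expand.grid(grid1, grid1, grid1, grid1))
  etas <- X %*% t(grid)
  vals <- -colSums(y * etas - log1p(exp(etas))) + ridge * rowSums(grid^2)
  start <- grid[which.min(vals), ]
  o <- stats::optim(start, nll, method = "Nelder-Mead",
                    control = list(maxit = 5000, reltol = 1e-14))
  o <- stats::optim(o$par, nll, method = "BFGS",
                    control = list(maxit = 1000, reltol = 1e-14))
  unname(o$par)
}

# Random stay-row instance with non-degenerate design
random_stay_rows <- function(n_rows, subject = "s1") {
  repeat {
    r <- sample(c(-1L, 1L), n_rows, replace = TRUE)
    t <- sample(c(-1L, 1L), n_rows, replace = TRUE)
    b <- stats::rnorm(4, 0, 0.7)
    eta <- b[1] + b[2] * r + b[3] * t + b[4] * r * t
    y <- stats::rbinom(n_rows, 1, stats::plogis(eta))
    rows <- data.frame(subject = subject, stay = y, prev_reward = r,
                       prev_transition = t, session = 1L, block = 1L,
                       trial = seq_len(n_rows), stringsAsFactors = FALSE)
    # require both outcomes in every (r, t) cell: the saturated model's MLE
    # is then finite and interior, so a tight oracle comparison is meaningful
    cell <- interaction(r, t)
    tab <- table(cell, y)
    if (nrow(tab) == 4L && ncol(tab) == 2L && all(tab >= 2L)) {
      return(rows)
    }
  }
}
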