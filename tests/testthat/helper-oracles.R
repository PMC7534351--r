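# Independent oracles used across the suite. These deliberately avoid the
# package's own QR/hat-matrix code paths: fits go through stats::lm on a
# data.frame, and leave-one-out is an explicit n-fold refit loop.

oracle_fit <- function(X, y) {
  df <- data.frame(y = y, X)
  m <- lm(y ~ ., data = df)
  s <- summary(m)
  list(
    coefficients = coef(m),
    r.squared = s$r.squared,
    sigma = s$sigma,
    fstatistic = unname(s$fstatistic[1])
  )
}

oracle_loo <- function(X, y) {
  n <- length(y)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    df <- data.frame(y = y[-i], X[-i, , drop = FALSE])
    m <- lm(y ~ ., data = df)
    pred[i] <- predict(m, newdata = as.data.frame(X)[i, , drop = FALSE])
  }
  press <- sum((y - pred)^2)
  list(pred = pred, press = press,
       q.squared = 1 - press / sum((y - mean(y))^2))
}

# Random well-conditioned regression problem with named descriptor columns.
random_problem <- function(n, p, seed, noise_sd = 0.3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("D", seq_len(p))))
    beta <- rnorm(p)
    y <- 1 + as.numeric(X %*% beta) + rnorm(n, sd = noise_sd)
    list(X = X, y = y)
  })
}

# In-memory descriptor table with one response and planted linear signal.
toy_table <- function(n = 12, p = 3, seed = 42) {
  prob <- random_problem(n, p, seed)
  descriptor_table(
    data.frame(compound = paste0("c", seq_len(n)), pIC50 = prob$y, prob$X),
    response_cols = "pIC50"
  )
}
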