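# Shared fixtures: tiny geometries and distributions built in code.

# axis-aligned square TC polygon, IF = its boundary
square_annotation <- function(side_um = 1000, margin_um = 300, im_width = 100) {
  lo <- margin_um
  hi <- margin_um + side_um
  poly <- cbind(c(lo, hi, hi, lo), c(lo, lo, hi, hi))
  tumor_annotation(poly, extent = c(0, hi + margin_um, 0, hi + margin_um),
                   im_width = im_width)
}

# uniform random points in a rectangle
runif_points <- function(n, xlim, ylim) {
  tibble::tibble(x = stats::runif(n, xlim[1], xlim[2]),
                 y = stats::runif(n, ylim[1], ylim[2]))
}

# symmetric Dirichlet draw (via gammas), for random tile distributions
rdirichlet1 <- function(k, alpha = 1) {
  g <- stats::rgamma(k, alpha)
  g / sum(g)
}

# independent Morisita-Horn evaluation, written directly from the formula
mh_oracle <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  2 * sum(p * q) / (sum(p^2) + sum(q^2))
}

# two-sample pooled-variance t statistic, closed form
t_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * stats::var(a) + (n2 - 1) * stats::var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# two-group log-rank chi-square computed from first principles
logrank_oracle <- function(time, event, group) {
  group <- as.integer(as.factor(group))
  stopifnot(all(group %in% 1:2))
  times <- sort(unique(time[event == 1]))
  O1 <- 0; E1 <- 0; V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == 1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}
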