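# Independent maximum-likelihood oracle: direct minimization of the binomial
# negative log-likelihood over (intercept, slope), no reuse of the IRLS path.
oracle_ml <- function(c_g, y, n, link) {
  lk <- stats::make.link(switch(link, linear = "identity", link))
  nll <- function(b) {
    mu <- lk$linkinv(b[1] + b[2] * c_g)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    -sum(y * log(mu) + (n - y) * log1p(-mu))
  }
  p <- pmin(pmax((y + 0.5) / (n + 1), 1e-6), 1 - 1e-6)
  start <- coef(lm(lk$linkfun(p) ~ c_g))
  fit <- optim(start, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  fit <- optim(fit$par, nll, method = "Nelder-Mead",
               control = list(reltol = 1e-14, maxit = 5000))
  list(par = unname(fit$par), nll = nll)
}
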