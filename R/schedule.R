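# Noise schedules and the forward / reverse diffusion primitives.
#
# The forward chain is variance preserving:
#   q(x_t | x_{t-1}) = N(sqrt(1 - beta_t) x_{t-1}, beta_t I),
# with the closed-form marginal
#   x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) eps,   abar_t = prod(1 - beta_s).
# The reverse step uses the epsilon parameterization with fixed variance
# beta_t I.

#' Build a diffusion noise schedule
#'
#' `linear`: beta_t equally spaced from 1e-4 to 0.02 inclusive (the standard
#' DDPM schedule). `polynomial`: abar_t = (1 - (t/T)^p)^2 with betas derived
#' from successive abar ratios and clipped to `[1e-5, 0.999]` for numerical
#' stability near t = T; used by the R-group stage.
#'
#' @param kind `"linear"` or `"polynomial"`.
#' @param T_steps Number of diffusion steps (at least 2).
#' @param p Polynomial power (polynomial schedule only).
#' @return An object of class `fd_schedule` with fields `kind`, `T`, `beta`,
#'   `alpha`, `alpha_bar`.
#' @export
fd_make_schedule <- function(kind = c("linear", "polynomial"), T_steps = 100L,
                             p = 2) {
  kind <- match.arg(kind)
  T_steps <- as.integer(T_steps)
  if (T_steps < 2) stop("T_steps must be at least 2")
  if (kind == "linear") {
    beta <- seq(1e-4, 0.02, length.out = T_steps)
    alpha_bar <- cumprod(1 - beta)
  } else {
    t_seq <- seq_len(T_steps)
    abar_raw <- (1 - (t_seq / T_steps)^p)^2
    abar_prev <- c(1, abar_raw[-T_steps])
    beta <- 1 - abar_raw / abar_prev
    beta <- pmin(pmax(beta, 1e-5), 0.999)
    alpha_bar <- cumprod(1 - beta)
  }
  structure(list(kind = kind, T = T_steps, beta = beta, alpha = 1 - beta,
                 alpha_bar = alpha_bar),
            class = "fd_schedule")
}

#' @export
print.fd_schedule <- function(x, ...) {
  cat("<fd_schedule> ", x$kind, ", T = ", x$T,
      ", beta in [", format(min(x$beta)), ", ", format(max(x$beta)),
      "], abar_T = ", format(x$alpha_bar[x$T]), "\n", sep = "")
  invisible(x)
}

.fd_check_t <- function(t, schedule, min_t = 1) {
  if (length(t) != 1 || t < min_t || t > schedule$T) {
    stop("t must be in [", min_t, ", ", schedule$T, "]")
  }
  as.integer(t)
}

.fd_check_shape <- function(x, noise) {
  if (!identical(dim(as.matrix(x)), dim(as.matrix(noise)))) {
    stop("noise must have the same shape as the state")
  }
}

#' Single forward diffusion step
#'
#' `x_t = sqrt(1 - beta_t) x_{t-1} + sqrt(beta_t) noise`.
#'
#' @param x_prev State at t-1 (any numeric array).
#' @param t Step index in 1..T.
#' @param schedule An [fd_make_schedule()] object.
#' @param noise Gaussian noise of the same shape.
#' @return State at t.
#' @export
fd_forward_step <- function(x_prev, t, schedule, noise) {
  t <- .fd_check_t(t, schedule)
  .fd_check_shape(x_prev, noise)
  sqrt(1 - schedule$beta[t]) * x_prev + sqrt(schedule$beta[t]) * noise
}

#' Closed-form forward marginal
#'
#' `x_t = sqrt(abar_t) x_0 + sqrt(1 - abar_t) noise`; `t = 0` returns `x0`.
#'
#' @inheritParams fd_forward_step
#' @param x0 Clean state.
#' @return State at t.
#' @export
fd_forward_marginal <- function(x0, t, schedule, noise) {
  t <- .fd_check_t(t, schedule, min_t = 0)
  if (t == 0) return(x0)
  .fd_check_shape(x0, noise)
  sqrt(schedule$alpha_bar[t]) * x0 +
    sqrt(1 - schedule$alpha_bar[t]) * noise
}

#' Reverse (denoising) step with the epsilon parameterization
#'
#' `mu = (x_t - beta_t / sqrt(1 - abar_t) * eps_hat) / sqrt(alpha_t)`;
#' `x_{t-1} = mu + sqrt(beta_t) noise` for `t > 1`, and `x_0 = mu` at
#' `t = 1` (the final step is noiseless).
#'
#' @inheritParams fd_forward_step
#' @param x_t Current noisy state.
#' @param eps_hat Predicted noise, same shape as `x_t`.
#' @return State at t-1.
#' @export
fd_posterior_step <- function(x_t, eps_hat, t, schedule, noise = NULL) {
  t <- .fd_check_t(t, schedule)
  .fd_check_shape(x_t, eps_hat)
  mu <- (x_t - schedule$beta[t] / sqrt(1 - schedule$alpha_bar[t]) * eps_hat) /
    sqrt(schedule$alpha[t])
  if (t == 1 || is.null(noise)) return(mu)
  .fd_check_shape(x_t, noise)
  mu + sqrt(schedule$beta[t]) * noise
}

#' Diffusion training loss
#'
#' Mean squared difference between true and predicted noise over every
#' coordinate and feature component of the generated atoms.
#'
#' @param eps,eps_hat Numeric arrays of identical shape.
#' @return Scalar loss.
#' @export
fd_diffusion_loss <- function(eps, eps_hat) {
  .fd_check_shape(eps, eps_hat)
  mean((as.numeric(eps) - as.numeric(eps_hat))^2)
}
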