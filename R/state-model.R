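#' Bell-Evans kinetic parameters for one barrier
#'
#' k(F) = k0 exp(beta F delta_x): an intrinsic (zero-force) rate `k0` and a
#' force-independent distance to the transition state `delta_x`.
#'
#' @param k0 Intrinsic rate in 1/s (> 0).
#' @param delta_x Distance to the transition state in nm (> 0).
#' @return An object of class `be_params`.
#' @examples
#' be_params(0.1, 0.5)
#' @export
be_params <- function(k0, delta_x) {
  if (!is.numeric(k0) || length(k0) != 1L || k0 <= 0)
    stop("k0 must be a single value > 0 (1/s)")
  if (!is.numeric(delta_x) || length(delta_x) != 1L || delta_x <= 0)
    stop("delta_x must be a single value > 0 (nm)")
  structure(list(k0 = k0, delta_x = delta_x), class = "be_params")
}

#' @export
print.be_params <- function(x, ...) {
  cat(sprintf("<be_params> k0 = %g 1/s, delta_x = %g nm\n", x$k0, x$delta_x))
  invisible(x)
}

#' Bell-Evans off-rate at a given force
#'
#' @param params A [be_params()] object.
#' @param force Force in pN (vectorised, >= 0).
#' @param ctx A [thermal_context()].
#' @return Off-rate in 1/s.
#' @export
bell_rate <- function(params, force, ctx = thermal_context()) {
  stopifnot(inherits(params, "be_params"))
  params$k0 * exp(ctx$beta * force * params$delta_x)
}

#' Three-state bond model with rupture and transition edges
#'
#' Encodes the kinetic graph of a receptor:ligand complex that can unbind
#' through three pathways: the native state N ruptures through P0, the
#' intermediates I1 and I2 rupture through P1 and P2. Forward transitions
#' N -> I1 -> I2 are always present; reverse transitions I1 -> N and
#' I2 -> I1 are present iff the model is reversible. Every edge carries
#' Bell-Evans parameters.
#'
#' @param rupture Named list with elements `P0`, `P1`, `P2`, each a
#'   [be_params()].
#' @param forward Named list with elements `N_I1`, `I1_I2`, each a
#'   [be_params()].
#' @param reverse `NULL` for an irreversible model, or a named list with
#'   elements `I1_N`, `I2_I1`, each a [be_params()].
#' @return An object of class `state_model`.
#' @examples
#' m <- state_model(
#'   rupture = list(P0 = be_params(5, 0.8), P1 = be_params(0.5, 0.3),
#'                  P2 = be_params(0.1, 0.1)),
#'   forward = list(N_I1 = be_params(0.2, 1.0), I1_I2 = be_params(0.2, 1.0)),
#'   reverse = list(I1_N = be_params(20, 0.05), I2_I1 = be_params(20, 0.05)))
#' @export
state_model <- function(rupture, forward, reverse = NULL) {
  need <- function(lst, nms, what) {
    if (!is.list(lst) || !setequal(names(lst), nms) ||
        !all(vapply(lst, inherits, logical(1), "be_params")))
      stop(sprintf("`%s` must be a named list of be_params with elements %s",
                   what, paste(nms, collapse = ", ")))
  }
  need(rupture, c("P0", "P1", "P2"), "rupture")
  need(forward, c("N_I1", "I1_I2"), "forward")
  if (!is.null(reverse)) need(reverse, c("I1_N", "I2_I1"), "reverse")
  structure(
    list(rupture = rupture, forward = forward, reverse = reverse,
         reversible = !is.null(reverse)),
    class = "state_model"
  )
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> %s transitions\n",
              if (x$reversible) "reversible" else "irreversible"))
  fmt <- function(nm, b) sprintf("  %-6s k0 = %-10g dx = %g\n", nm, b$k0, b$delta_x)
  for (nm in names(x$rupture)) cat(fmt(nm, x$rupture[[nm]]))
  for (nm in names(x$forward)) cat(fmt(nm, x$forward[[nm]]))
  if (x$reversible) for (nm in names(x$reverse)) cat(fmt(nm, x$reverse[[nm]]))
  invisible(x)
}

#' Single-pathway (slip-bond) model
#'
#' Convenience constructor: a state model whose only nonzero rate is P0
#' rupture from N. Transition rates are set to a negligible floor so the
#' kinetic graph keeps its shape while all probability flows through P0.
#'
#' @param params A [be_params()] for the single rupture barrier.
#' @return A `state_model`.
#' @export
single_state_model <- function(params) {
  off <- be_params(1e-300, 1e-6)
  state_model(
    rupture = list(P0 = params, P1 = off, P2 = off),
    forward = list(N_I1 = off, I1_I2 = off)
  )
}

# Flatten a state_model into the edge table consumed by the C++ core.
# States: 0 = N, 1 = I1, 2 = I2; edge_to -1 = unbound.
model_edges <- function(model) {
  stopifnot(inherits(model, "state_model"))
  from <- c(0L, 1L, 2L, 0L, 1L)
  to <- c(-1L, -1L, -1L, 1L, 2L)
  pathway <- c(0L, 1L, 2L, -1L, -1L)
  pars <- c(model$rupture[c("P0", "P1", "P2")],
            model$forward[c("N_I1", "I1_I2")])
  if (model$reversible) {
    from <- c(from, 1L, 2L)
    to <- c(to, 0L, 1L)
    pathway <- c(pathway, -1L, -1L)
    pars <- c(pars, model$reverse[c("I1_N", "I2_I1")])
  }
  list(from = from, to = to, pathway = pathway,
       k0 = vapply(pars, `[[`, numeric(1), "k0"),
       dx = vapply(pars, `[[`, numeric(1), "delta_x"))
}

#' Replace the transition-edge parameters of a model
#'
#' @param model A [state_model()] skeleton (rupture edges kept as-is).
#' @param theta Numeric vector of transition parameters in the order
#'   `N_I1.k0, N_I1.dx, I1_I2.k0, I1_I2.dx` and, for reversible models,
#'   `I1_N.k0, I1_N.dx, I2_I1.k0, I2_I1.dx`.
#' @return A `state_model` with the transition edges set from `theta`.
#' @export
set_transition_params <- function(model, theta) {
  stopifnot(inherits(model, "state_model"))
  n_need <- if (model$reversible) 8L else 4L
  if (length(theta) != n_need)
    stop(sprintf("theta must have length %d for this model", n_need))
  model$forward$N_I1 <- be_params(theta[1], theta[2])
  model$forward$I1_I2 <- be_params(theta[3], theta[4])
  if (model$reversible) {
    model$reverse$I1_N <- be_params(theta[5], theta[6])
    model$reverse$I2_I1 <- be_params(theta[7], theta[8])
  }
  model
}

#' Extract the transition-edge parameters of a model
#'
#' Inverse of [set_transition_params()].
#' @param model A [state_model()].
#' @return Named numeric vector of transition parameters.
#' @export
get_transition_params <- function(model) {
  stopifnot(inherits(model, "state_model"))
  out <- c(N_I1.k0 = model$forward$N_I1$k0, N_I1.dx = model$forward$N_I1$delta_x,
           I1_I2.k0 = model$forward$I1_I2$k0, I1_I2.dx = model$forward$I1_I2$delta_x)
  if (model$reversible)
    out <- c(out,
             I1_N.k0 = model$reverse$I1_N$k0, I1_N.dx = model$reverse$I1_N$delta_x,
             I2_I1.k0 = model$reverse$I2_I1$k0, I2_I1.dx = model$reverse$I2_I1$delta_x)
  out
}

#' Default three-state reversible catch-bond model
#'
#' A reference parameter set with the landscape ordering that produces
#' catch-bond behaviour: the distance to the transition state decreases
#' from P0 to P2 (0.8, 0.3, 0.12 nm) while the barrier stability increases
#' (intrinsic rates 5, 0.5, 0.1 1/s), forward transitions are strongly
#' force-promoted and reverse transitions are fast at low force. Under
#' force clamp this model's mean lifetime rises and then falls with an
#' interior maximum (slip-catch-slip). Used as the ground-truth generator
#' default throughout the synthetic-data module.
#'
#' @param reversible Include reverse transition edges (default TRUE).
#' @return A `state_model`.
#' @export
default_state_model <- function(reversible = TRUE) {
  state_model(
    rupture = list(P0 = be_params(5, 0.8),
                   P1 = be_params(0.5, 0.3),
                   P2 = be_params(0.1, 0.12)),
    forward = list(N_I1 = be_params(0.2, 1.0),
                   I1_I2 = be_params(0.2, 1.0)),
    reverse = if (reversible)
      list(I1_N = be_params(20, 0.05), I2_I1 = be_params(20, 0.05))
  )
}
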