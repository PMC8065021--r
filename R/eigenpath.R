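#' Trace matched eigenvalue branches along a parameter segment
#'
#' Walks a straight line segment in parameter space (typically from the
#' decoupled bifurcation point `P0 = (0, alpha0)` to a coupled-cell
#' bifurcation value `P1 = (c*, alpha*)`), re-solving the equilibrium and
#' computing the full Jacobian spectrum at each step, and matching
#' eigenvalues between consecutive steps by a globally greedy
#' minimal-distance assignment in the complex plane. Conjugate symmetry is
#' preserved by construction (the spectrum of a real matrix), and branches
#' are reported through their `Im >= 0` representatives plus the real
#' eigenvalues.
#'
#' At a degenerate start (identical cells at `c = 0` carry a double
#' imaginary pair) the branch ordering is fixed retrospectively: the branch
#' that is (closest to) purely imaginary at the end of the segment is
#' labelled branch 1, matching the convention of naming the bifurcating
#' branch first.
#'
#' @param model A `cell_model` template.
#' @param from,to Named lists of parameter values defining the segment
#'   endpoints, e.g. `list(coupling = 0, alpha = 0.545)`.
#' @param steps Number of steps (the path has `steps + 1` points).
#' @param guess Optional equilibrium seed for the first point.
#' @return Object of class `eigen_path`: list with `parameters` (data.frame
#'   of the swept values), `eigenvalues` (complex matrix, one row per step,
#'   branch-matched columns), `unstable_dims` (integer vector of counts of
#'   eigenvalues with positive real part), `equilibria` (matrix of states).
#' @export
trace_segment <- function(model, from, to, steps = 200, guess = NULL) {
  stopifnot(inherits(model, "cell_model"), steps >= 1,
            identical(sort(names(from)), sort(names(to))))
  ts <- seq(0, 1, length.out = steps + 1)
  pars <- sapply(names(from), function(nm)
    (1 - ts) * from[[nm]] + ts * to[[nm]])
  pars <- matrix(pars, ncol = length(from),
                 dimnames = list(NULL, names(from)))
  m <- model$m
  ev_mat <- matrix(NA_complex_, steps + 1, m)
  states <- matrix(NA_real_, steps + 1, m)
  nunst <- integer(steps + 1)
  warm <- guess
  truncated <- FALSE
  for (k in seq_len(steps + 1)) {
    md <- do.call(update_model, c(list(model), as.list(pars[k, ])))
    eq <- tryCatch(solve_equilibrium(md, guess = warm), error = identity)
    if (inherits(eq, "error")) {
      warning(sprintf("equilibrium solve failed at step %d (%s); path truncated",
                      k, conditionMessage(eq)))
      truncated <- TRUE
      k <- k - 1
      break
    }
    warm <- eq$state
    states[k, ] <- eq$state
    ev <- eigen(model_jacobian(md, eq$state), only.values = TRUE)$values
    if (k == 1) {
      ev_mat[1, ] <- ev[order(-Im(ev), Re(ev))]
    } else {
      ev_mat[k, ] <- .match_eigs(ev_mat[k - 1, ], ev)
    }
    nunst[k] <- sum(Re(ev) > 0)
  }
  keep <- seq_len(if (truncated) k else steps + 1)
  # retrospective ordering: put the branch ending nearest the imaginary
  # axis (with positive imaginary part) first among the complex branches
  evk <- ev_mat[keep, , drop = FALSE]
  lastev <- evk[nrow(evk), ]
  cplx <- which(Im(lastev) > 1e-9)
  if (length(cplx) > 1) {
    ord <- cplx[order(abs(Re(lastev[cplx])))]
    rest <- setdiff(seq_len(m), cplx)
    perm <- c(ord, rest)
    evk <- evk[, perm, drop = FALSE]
  }
  structure(list(parameters = as.data.frame(pars[keep, , drop = FALSE]),
                 eigenvalues = evk,
                 unstable_dims = nunst[keep],
                 equilibria = states[keep, , drop = FALSE],
                 truncated = truncated),
            class = "eigen_path")
}

# globally greedy assignment: repeatedly take the smallest entry of the
# cross-distance matrix; adequate for smooth, well-separated branches
.match_eigs <- function(prev, cur) {
  m <- length(prev)
  D <- abs(outer(prev, cur, `-`))
  out <- complex(m)
  taken_r <- logical(m); taken_c <- logical(m)
  for (i in seq_len(m)) {
    D2 <- D
    D2[taken_r, ] <- Inf; D2[, taken_c] <- Inf
    ij <- arrayInd(which.min(D2), dim(D2))
    out[ij[1]] <- cur[ij[2]]
    taken_r[ij[1]] <- TRUE; taken_c[ij[2]] <- TRUE
  }
  out
}

#' @export
print.eigen_path <- function(x, ...) {
  cat(sprintf("<eigen_path> %d points, dimension %d%s\n",
              nrow(x$eigenvalues), ncol(x$eigenvalues),
              if (isTRUE(x$truncated)) " (truncated)" else ""))
  cat("  unstable dimensions along path:",
      paste(unique(x$unstable_dims), collapse = " -> "), "\n")
  invisible(x)
}

#' Classify the stability transition along an eigenvalue path
#'
#' Summarises each branch of an [trace_segment()] path: its maximum real
#' part along the path and whether it crosses the imaginary axis, plus the
#' sequence of unstable-manifold dimensions. Distinguishes the signature in
#' which a branch makes an excursion into the right half-plane mid-segment
#' (`"right_half_plane_excursion"`, Hill-type in the reference examples)
#' from the one where every non-bifurcating branch stays in the left
#' half-plane until the endpoint (`"stays_left"`).
#'
#' @param path An `eigen_path`.
#' @return List with `branch_summary` (data.frame: branch, max_re,
#'   crosses_imaginary_axis), `unstable_dims`, and `signature`.
#' @export
classify_transition <- function(path) {
  stopifnot(inherits(path, "eigen_path"))
  ev <- path$eigenvalues
  np <- nrow(ev)
  maxre <- apply(Re(ev), 2, max)
  crosses <- apply(Re(ev), 2, function(r) any(r[-np] < 0 & r[-1] >= 0) ||
                     any(r[-np] >= 0 & r[-1] < 0))
  interior_unstable <- if (np > 2) any(path$unstable_dims[2:(np - 1)] > 0) else FALSE
  structure(list(
    branch_summary = data.frame(branch = seq_len(ncol(ev)),
                                max_re = maxre,
                                crosses_imaginary_axis = crosses),
    unstable_dims = path$unstable_dims,
    signature = if (interior_unstable) "right_half_plane_excursion" else "stays_left"),
    class = "transition_summary")
}

#' @export
print.transition_summary <- function(x, ...) {
  cat("<transition_summary>", x$signature, "\n")
  print(x$branch_summary, row.names = FALSE)
  invisible(x)
}
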