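# Domain types for the GARD kinetics: buffered environment, catalytic
# rate-enhancement matrix, and a single micellar assembly.

#' Physical constants used by the order/complexity metrics
#'
#' Boltzmann's constant (J/K), Avogadro's number (1/mol) and the molar gas
#' constant R = k_B * N_A (J/(K*mol)), at their CODATA 2018 exact values.
#'
#' @format A named list with elements `k_B`, `N_A`, `R`.
#' @export
gard_constants <- list(
  k_B = 1.380649e-23,
  N_A = 6.02214076e23,
  R   = 1.380649e-23 * 6.02214076e23
)

#' Buffered amphiphile environment
#'
#' The external milieu of the GARD model: `n_types` amphiphile species held at
#' constant fractional concentrations `pi` (the environment is buffered, so
#' accretion never depletes it), with per-type forward and backward rate
#' constants for monomer entry into / exit from an assembly.
#'
#' @param pi Numeric vector of external fractional concentrations
#'   \eqn{\pi_i}; must be nonnegative and sum to 1.
#' @param k_fwd Forward rate constants \eqn{k_i} (1/time); scalar or one per
#'   type.
#' @param k_bwd Backward rate constants \eqn{k_{-i}} (1/time); scalar or one
#'   per type.
#' @return An object of class `gard_environment` with fields `n_types`, `pi`,
#'   `k_fwd`, `k_bwd`.
#' @examples
#' env <- gard_environment(rep(1 / 10, 10))
#' env$n_types
#' @export
gard_environment <- function(pi, k_fwd = 1, k_bwd = 0.2) {
  pi <- as.numeric(pi)
  n <- length(pi)
  if (n < 1L) stop("`pi` must have at least one entry", call. = FALSE)
  if (any(pi < 0)) stop("all entries of `pi` must be >= 0", call. = FALSE)
  if (abs(sum(pi) - 1) > 1e-12) {
    stop("`pi` must sum to 1 (got ", format(sum(pi), digits = 15), ")",
         call. = FALSE)
  }
  k_fwd <- rep_len(as.numeric(k_fwd), n)
  k_bwd <- rep_len(as.numeric(k_bwd), n)
  if (any(k_fwd <= 0) || any(k_bwd <= 0)) {
    stop("all rate constants must be > 0", call. = FALSE)
  }
  structure(
    list(n_types = n, pi = pi, k_fwd = k_fwd, k_bwd = k_bwd),
    class = "gard_environment"
  )
}

#' @export
print.gard_environment <- function(x, ...) {
  cat("<gard_environment> ", x$n_types, " amphiphile types\n", sep = "")
  cat("  pi: ", paste(signif(x$pi, 3), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Validate a catalytic rate-enhancement matrix
#'
#' The beta matrix holds the dimensionless mutual-catalysis factors
#' \eqn{\beta_{ij}}: the rate enhancement of type-i accretion caused by a
#' molecule of type j already resident in the assembly.
#'
#' @param beta Square numeric matrix, all entries nonnegative.
#' @param n_types Optional expected dimension (checked when supplied).
#' @return The validated matrix, invisibly classed as `gard_beta`.
#' @export
beta_matrix <- function(beta, n_types = NULL) {
  beta <- as.matrix(beta)
  if (nrow(beta) != ncol(beta)) {
    stop("beta matrix must be square (got ", nrow(beta), "x", ncol(beta), ")",
         call. = FALSE)
  }
  if (!is.numeric(beta) || anyNA(beta)) {
    stop("beta matrix must be numeric with no missing values", call. = FALSE)
  }
  if (any(beta < 0)) stop("all beta entries must be >= 0", call. = FALSE)
  if (!is.null(n_types) && nrow(beta) != n_types) {
    stop("beta matrix is ", nrow(beta), "x", ncol(beta),
         " but the environment has ", n_types, " types", call. = FALSE)
  }
  dimnames(beta) <- NULL
  class(beta) <- c("gard_beta", class(beta))
  beta
}

#' One micellar assembly
#'
#' An assembly is an unordered composition: the integer count \eqn{n_i} of
#' molecules of each amphiphile type currently in the micelle.
#'
#' @param counts Nonnegative integer vector of per-type molecule counts.
#' @return An object of class `gard_assembly` with fields `counts` and `size`
#'   (the total molecule number N).
#' @examples
#' a <- assembly(c(3, 1, 0))
#' a$size
#' @export
assembly <- function(counts) {
  counts <- as.numeric(counts)
  if (any(counts < 0)) stop("assembly counts must be >= 0", call. = FALSE)
  size <- sum(counts)
  if (size < 1) stop("a live assembly must contain at least one molecule",
                     call. = FALSE)
  structure(list(counts = counts, size = size), class = "gard_assembly")
}

#' @export
print.gard_assembly <- function(x, ...) {
  cat("<gard_assembly> N = ", x$size, "; counts: ",
      paste(x$counts, collapse = " "), "\n", sep = "")
  invisible(x)
}

# Accept either a gard_assembly or a raw counts vector.
as_counts <- function(x) {
  if (inherits(x, "gard_assembly")) x$counts else as.numeric(x)
}

check_dims <- function(counts, env, beta) {
  n <- env$n_types
  if (length(counts) != n) {
    stop("assembly has ", length(counts), " types but environment has ", n,
         call. = FALSE)
  }
  if (nrow(beta) != n || ncol(beta) != n) {
    stop("beta matrix is ", nrow(beta), "x", ncol(beta),
         " but environment has ", n, " types", call. = FALSE)
  }
  invisible(TRUE)
}

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
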