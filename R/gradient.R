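#' Construct a gradient scheme
#'
#' @param bvals numeric vector of b-values (s/mm^2).
#' @param bvecs 3 x K matrix of gradient directions; columns for b = 0
#'   measurements may be zero.
#' @return A \linkS4class{GradientScheme}.
#' @export
gradientScheme <- function(bvals, bvecs) {
    new("GradientScheme", bvals = as.numeric(bvals),
        bvecs = matrix(as.numeric(bvecs), nrow = 3))
}

#' Evenly spread unit directions on the hemisphere
#'
#' Spherical Fibonacci lattice restricted to the upper hemisphere, the usual
#' deterministic stand-in for an electrostatically optimised diffusion
#' sampling scheme.  Antipodal symmetry of the diffusion signal makes the
#' hemisphere sufficient.
#'
#' @param n number of directions.
#' @return 3 x n matrix of unit vectors.
#' @export
fibonacciDirections <- function(n) {
    stopifnot(n >= 1)
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- i / n                      # upper hemisphere only
    r <- sqrt(pmax(0, 1 - z^2))
    rbind(r * cos(phi), r * sin(phi), z)
}

#' Default acquisition schemes
#'
#' \code{acquisitionScheme()} builds a single-shell scheme with one b = 0
#' reference.  The full-resolution default (126 directions at
#' b = 3000 s/mm^2) mirrors a long ex vivo acquisition; a reduced
#' 30-direction scheme is the package's default for phantom work.
#'
#' @param nDirections number of diffusion-weighted directions.
#' @param b shell b-value, s/mm^2.
#' @return A \linkS4class{GradientScheme}; the b = 0 measurement comes first.
#' @export
acquisitionScheme <- function(nDirections = 30, b = 3000) {
    dirs <- fibonacciDirections(nDirections)
    gradientScheme(c(0, rep(b, nDirections)), cbind(c(0, 0, 0), dirs))
}

#' Read / write FSL-dialect gradient tables
#'
#' \code{.bval} is one whitespace-separated row of b-values; \code{.bvec}
#' is three rows (x, y, z components).  Gradients are interpreted in image
#' coordinates; no scanner-frame reorientation is applied.
#'
#' @param bvalPath,bvecPath file paths.
#' @return \code{readBvalBvec}: a \linkS4class{GradientScheme}.
#' @export
readBvalBvec <- function(bvalPath, bvecPath) {
    bvals <- scan(bvalPath, quiet = TRUE)
    bv <- scan(bvecPath, quiet = TRUE)
    if (length(bv) != 3 * length(bvals))
        stop("bvec/bval length mismatch: ", length(bv) / 3, " directions vs ",
             length(bvals), " b-values")
    if (all(bvals == 0))
        stop("no diffusion weighting: all b-values are zero")
    gradientScheme(bvals, matrix(bv, nrow = 3, byrow = TRUE))
}

#' @rdname readBvalBvec
#' @param scheme a \linkS4class{GradientScheme}.
#' @export
writeBvalBvec <- function(scheme, bvalPath, bvecPath) {
    writeLines(paste(format(scheme@bvals, trim = TRUE), collapse = " "),
               bvalPath)
    writeLines(apply(scheme@bvecs, 1L, function(r)
        paste(format(r, trim = TRUE, digits = 10), collapse = " ")),
        bvecPath)
    invisible(c(bvalPath, bvecPath))
}
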