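## Blind-SIM joint object / illumination estimation.
##
## Model: camera frame m is M_m = D(H (*) (rho * I_m)) + noise, with rho the
## object on a fine grid (camera pixel / u), I_m the unknown illumination
## patterns, H the detection PSF and D the u x u camera binning. The patterns
## are constrained to add up to a uniform field, sum_m I_m = M * I0; the
## constraint is eliminated exactly by expressing the last pattern through
## the others. Each block subproblem (object for fixed patterns, patterns
## for fixed object) is linear least squares; minimization alternates a few
## conjugate-gradient iterations per block with nonnegativity projection and
## a backtracking safeguard, so the objective is non-increasing at every
## accepted iteration.

#' Options for blind-SIM reconstruction
#'
#' @param upsample reconstruction upsampling factor u (recon pixel =
#'   camera pixel / u), 1 to 5 (1 = camera-grid reconstruction, mainly for
#'   exact-recovery checks)
#' @param max_iter maximum number of outer iterations
#' @param tol stop when the relative objective decrease over one iteration
#'   falls below this
#' @param tikhonov weight of the smoothing penalty sum_m ||grad I_m||^2
#'   stabilizing the bilinear problem
#' @param inner_rho,inner_illum conjugate-gradient iterations per block per
#'   outer iteration
#' @param i0 uniform illumination level the patterns sum to (M * i0);
#'   1 for unit-mean normalized patterns
#' @param estimate_illumination set FALSE to freeze supplied illumination
#'   patterns (the reconstruction then reduces to a positivity-constrained
#'   deconvolution of the object)
#' @param seed seed for the optional random jitter of the initial object
#' @param init_jitter relative sd of multiplicative jitter on the initial
#'   object (0 = deterministic initialization)
#' @return list of class `recon_options`
#' @export
recon_options <- function(upsample = 3L, max_iter = 40L, tol = 1e-6,
                          tikhonov = 1e-3, i0 = 1,
                          estimate_illumination = TRUE, seed = NULL,
                          init_jitter = 0, inner_rho = 10L,
                          inner_illum = 10L) {
  stopifnot(upsample %in% 1:5, tol > 0, max_iter >= 1)
  structure(list(upsample = as.integer(upsample),
                 max_iter = as.integer(max_iter), tol = tol,
                 tikhonov = tikhonov, i0 = i0,
                 estimate_illumination = estimate_illumination,
                 seed = seed, init_jitter = init_jitter,
                 inner_rho = as.integer(inner_rho),
                 inner_illum = as.integer(inner_illum)),
            class = "recon_options")
}

#' Minimum frame count for a target resolution gain
#'
#' Information-counting bound: an N-fold resolution improvement needs at
#' least N^2 sub-frames; with an oversampling factor alpha the practical
#' count is ceiling(alpha * N^2).
#'
#' @param gain resolution improvement factor N, >= 1
#' @param oversampling oversampling factor alpha, >= 1
#' @return integer frame count
#' @examples
#' min_frames(3)      # 9
#' min_frames(4, 2)   # 32
#' @export
min_frames <- function(gain, oversampling = 1) {
  stopifnot(gain >= 1, oversampling >= 1)
  as.integer(ceiling(oversampling * gain^2))
}

## ---- batched linear operators -------------------------------------------

#' @keywords internal
bin_stack <- function(a, b) {
  if (b == 1L) return(a)
  d <- dim(a)
  nc1 <- d[1L] %/% b
  g1 <- rep(seq_len(nc1), each = b)
  m <- rowsum(matrix(a, d[1L], d[2L] * d[3L]), g1, reorder = FALSE)
  a2 <- aperm(array(m, c(nc1, d[2L], d[3L])), c(2L, 1L, 3L))
  nc2 <- d[2L] %/% b
  g2 <- rep(seq_len(nc2), each = b)
  m2 <- rowsum(matrix(a2, d[2L], nc1 * d[3L]), g2, reorder = FALSE)
  aperm(array(m2, c(nc2, nc1, d[3L])), c(2L, 1L, 3L))
}

#' @keywords internal
binT_stack <- function(r, b) {
  if (b == 1L) return(r)
  d <- dim(r)
  r[rep(seq_len(d[1L]), each = b), rep(seq_len(d[2L]), each = b), ,
    drop = FALSE]
}

#' @keywords internal
pad_stack <- function(a, p) {
  if (p == 0L) return(a)
  d <- dim(a)
  ri <- c(p:1, 1:d[1L], d[1L]:(d[1L] - p + 1L))
  ci <- c(p:1, 1:d[2L], d[2L]:(d[2L] - p + 1L))
  a[ri, ci, , drop = FALSE]
}

## adjoint of pad_stack: fold reflected borders back onto their sources
#' @keywords internal
padT_stack <- function(a, p, n1, n2) {
  if (p == 0L) return(a)
  d <- dim(a)
  ri <- c(p:1, 1:n1, n1:(n1 - p + 1L))
  ci <- c(p:1, 1:n2, n2:(n2 - p + 1L))
  m <- rowsum(matrix(a, d[1L], d[2L] * d[3L]), ri, reorder = TRUE)
  a2 <- aperm(array(m, c(n1, d[2L], d[3L])), c(2L, 1L, 3L))
  m2 <- rowsum(matrix(a2, d[2L], n1 * d[3L]), ci, reorder = TRUE)
  aperm(array(m2, c(n2, n1, d[3L])), c(2L, 1L, 3L))
}

#' @keywords internal
crop_stack <- function(a, p, n1, n2) {
  if (p == 0L) return(a)
  a[(p + 1L):(p + n1), (p + 1L):(p + n2), , drop = FALSE]
}

## Reflective-boundary PSF convolution of every slice (and its exact
## adjoint), precomputed for a fixed fine-grid size.
#' @keywords internal
make_stack_convolver <- function(n1, n2, kernel) {
  kr <- (nrow(kernel) - 1L) %/% 2L
  kmax <- min(n1, n2) - 1L
  if (kr > kmax) {   # trim an oversized kernel to the image size
    keep <- (kr - kmax + 1L):(kr + kmax + 1L)
    kernel <- kernel[keep, keep]
    kernel <- kernel / sum(kernel)
    kr <- kmax
  }
  p <- kr
  m1 <- n1 + 2L * p; m2 <- n2 + 2L * p
  kbig <- matrix(0, m1, m2)
  kbig[((-kr:kr) %% m1) + 1L, ((-kr:kr) %% m2) + 1L] <- kernel[]
  ## even-symmetric kernel => real OTF, so two real slices can ride one
  ## complex FFT (slice pairs packed as real + i*imag)
  otf <- as.vector(Re(fft2(kbig)))
  conv_big <- function(big) {
    M <- dim(big)[3L]
    h <- (M + 1L) %/% 2L
    if (M > 1L) {
      packed <- big[, , 1:h, drop = FALSE] + (0 + 1i) *
        big[, , c((h + 1L):M, 1L)[seq_len(h)], drop = FALSE]
      out <- fft2_stack(fft2_stack(packed) * otf, inverse = TRUE)
      res <- array(0, dim(big))
      res[, , 1:h] <- Re(out)
      res[, , (h + 1L):M] <- Im(out)[, , seq_len(M - h), drop = FALSE]
      res
    } else {
      array(Re(fft2_stack(fft2_stack(big) * otf, inverse = TRUE)),
            dim(big))
    }
  }
  list(
    forward = function(a) {
      crop_stack(conv_big(pad_stack(a, p)), p, n1, n2)
    },
    adjoint = function(a) {
      d <- dim(a)
      big <- array(0, c(m1, m2, d[3L]))
      big[(p + 1L):(p + n1), (p + 1L):(p + n2), ] <- a
      padT_stack(conv_big(big), p, n1, n2)
    },
    pad = p)
}

## circular gradient penalty sum ||grad I||^2 and its gradient
#' @keywords internal
tik_cost <- function(I) {
  dx1 <- I - I[c(2:dim(I)[1L], 1L), , , drop = FALSE]
  dx2 <- I - I[, c(2:dim(I)[2L], 1L), , drop = FALSE]
  sum(dx1^2) + sum(dx2^2)
}

#' @keywords internal
tik_grad <- function(I) {
  d <- dim(I)
  s1 <- c(2:d[1L], 1L); s1b <- c(d[1L], 1:(d[1L] - 1L))
  s2 <- c(2:d[2L], 1L); s2b <- c(d[2L], 1:(d[2L] - 1L))
  2 * (4 * I - I[s1, , , drop = FALSE] - I[s1b, , , drop = FALSE] -
         I[, s2, , drop = FALSE] - I[, s2b, , drop = FALSE])
}

## ---- cost ----------------------------------------------------------------

#' Blind-SIM data-fidelity cost
#'
#' \eqn{\sum_m \| M_m - D(H \ast (\rho I_m)) \|^2} for an object estimate,
#' a set of illumination patterns, and an observed stack.
#'
#' @param rho object on the fine grid (matrix)
#' @param illumination fine-grid illumination patterns: 3-D array
#'   (n x n x M) or list of matrices / `speckle_pattern`s
#' @param stack observed `frame_stack` (camera grid)
#' @param psf `psf_model` sampled at the fine-grid pixel
#' @return scalar cost
#' @export
blindsim_cost <- function(rho, illumination, stack, psf) {
  I <- as_illum_array(illumination)
  nf <- nrow(rho)
  nc <- dim(stack$frames)[1L]
  if (nf %% nc != 0L || !all(dim(I)[1:2] == nf) ||
      dim(I)[3L] != dim(stack$frames)[3L])
    stop("shapes inconsistent: rho ", nf, ", patterns ",
         paste(dim(I), collapse = "x"), ", frames ",
         paste(dim(stack$frames), collapse = "x"))
  u <- nf %/% nc
  conv <- make_stack_convolver(nf, nf, psf$kernel)
  pred <- bin_stack(conv$forward(array(as.vector(rho) * as.vector(I),
                                       dim(I))), u)
  sum((pred - stack$frames)^2)
}

#' @keywords internal
as_illum_array <- function(illumination) {
  if (is.array(illumination) && length(dim(illumination)) == 3L)
    return(illumination)
  if (is.list(illumination)) {
    mats <- lapply(illumination, function(p)
      if (inherits(p, "speckle_pattern")) p$intensity else p)
    return(array(unlist(mats), c(dim(mats[[1L]]), length(mats))))
  }
  stop("illumination must be a 3-D array or a list of patterns")
}

## Conjugate gradients for SPD systems A x = b, x0 = 0, fixed iteration
## budget (the positivity projection and the monotone safeguard live in the
## caller). A is a function.
#' @keywords internal
cg_solve <- function(A, b, iters) {
  x <- b * 0
  r <- b
  p <- r
  rs <- sum(r * r)
  if (rs == 0) return(x)
  for (i in seq_len(iters)) {
    Ap <- A(p)
    pAp <- sum(p * Ap)
    if (!is.finite(pAp) || pAp <= 0) break
    al <- rs / pAp
    x <- x + al * p
    r <- r - al * Ap
    rs2 <- sum(r * r)
    if (rs2 < 1e-28) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  x
}

## ---- reconstruction ------------------------------------------------------

#' Blind-SIM reconstruction
#'
#' Jointly estimates the object and the illumination patterns from a
#' speckle-illuminated frame stack by alternating block minimization of
#' [blindsim_cost()] (plus a mild smoothing penalty on the patterns): each
#' block subproblem is linear least squares, attacked with a few conjugate-
#' gradient iterations followed by nonnegativity projection and a
#' backtracking safeguard, under the constraint that the patterns add up to
#' a uniform field. The object is initialized
#' from the upsampled mean frame and the patterns from the uniform field;
#' the objective is non-increasing over iterations and the run is
#' deterministic given the options.
#'
#' @param stack observed `frame_stack`; apply [normalize_stack()] first
#'   (per-frame unit mean) unless the frames are already calibrated
#' @param psf `psf_model` sampled at the reconstruction pixel
#'   (camera pixel / upsample)
#' @param options a [recon_options()] list
#' @param illumination optional known fine-grid patterns (3-D array or list)
#'   used as initialization - or, with
#'   `options$estimate_illumination = FALSE`, frozen so that only the object
#'   is estimated
#' @return object of class `recon_result`: `rho` (fine-grid estimate),
#'   `illumination` (n x n x M array), `cost` (objective history),
#'   `data_cost`, `converged`, `iterations`, `dx`, `options`
#' @export
reconstruct <- function(stack, psf, options = recon_options(),
                        illumination = NULL) {
  stopifnot(inherits(stack, "frame_stack"), inherits(psf, "psf_model"))
  frames <- stack$frames
  M <- dim(frames)[3L]
  if (M < 2L) stop("insufficient frames: blind-SIM needs at least 2")
  nc <- dim(frames)[1L]
  u <- options$upsample
  nf <- nc * u
  conv <- make_stack_convolver(nf, nf, psf$kernel)
  i0 <- options$i0
  lam <- options$tikhonov

  ## initialization: upsampled mean frame, uniform patterns
  mf <- apply(frames, c(1L, 2L), mean)
  rho <- pmax(mf, 0)[rep(seq_len(nc), each = u), rep(seq_len(nc), each = u)]
  rho <- rho / (u * u)
  if (options$init_jitter > 0) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(if (is.null(options$seed)) 0L else options$seed)
    rho <- rho * (1 + options$init_jitter * matrix(stats::rnorm(nf * nf),
                                                   nf, nf))
    rho <- pmax(rho, 0)
  }
  I <- if (is.null(illumination)) array(i0, c(nf, nf, M)) else {
    a <- as_illum_array(illumination)
    if (!all(dim(a) == c(nf, nf, M)))
      stop("supplied illumination has wrong shape")
    a
  }

  objective <- function(rho, I, pred = NULL) {
    if (is.null(pred))
      pred <- bin_stack(conv$forward(array(as.vector(rho) * as.vector(I),
                                           dim(I))), u)
    data <- sum((pred - frames)^2)
    list(data = data, total = data + lam * tik_cost(I), pred = pred)
  }

  forward_pred <- function(rho, I)
    bin_stack(conv$forward(array(as.vector(rho) * as.vector(I), dim(I))), u)

  ## project patterns: free patterns nonnegative, last pattern from the
  ## uniform-sum constraint, pixels driving it negative rescaled
  project_I <- function(I) {
    d <- dim(I)
    I[, , -d[3L]] <- pmax(I[, , -d[3L], drop = FALSE], 0)
    sumV <- apply(I[, , -d[3L], drop = FALSE], c(1L, 2L), sum)
    over <- sumV > d[3L] * i0
    if (any(over)) {
      fac <- matrix(1, d[1L], d[2L])
      fac[over] <- (d[3L] * i0) / sumV[over]
      I[, , -d[3L]] <- I[, , -d[3L], drop = FALSE] *
        as.vector(fac)
      sumV[over] <- d[3L] * i0
    }
    I[, , d[3L]] <- d[3L] * i0 - sumV
    I
  }
  I <- project_I(I)

  pred <- forward_pred(rho, I)
  ob <- objective(rho, I, pred)
  cost_hist <- ob$total
  step_rho <- NA_real_; step_I <- NA_real_
  converged <- FALSE
  it <- 0L

  while (it < options$max_iter) {
    it <- it + 1L
    accepted <- FALSE

    ## ---- object block: CG on the (linear) normal equations, then
    ##      projection with a monotone safeguard line search ----
    res <- pred - frames
    B <- conv$adjoint(binT_stack(res, u))          # H^T D^T r, per frame
    g_rho <- 2 * rowSums(array(as.vector(I) * as.vector(B), dim(B)),
                         dims = 2L)
    ## restrict the CG solve to the inactive set (pixels not pinned at the
    ## positivity bound with an outward gradient), so projection cannot
    ## cancel the step
    mask_r <- !(rho <= 0 & g_rho > 0)
    A_rho <- function(x) {
      x <- x * mask_r
      fx <- bin_stack(conv$forward(array(as.vector(x) * as.vector(I),
                                         dim(I))), u)
      Bx <- conv$adjoint(binT_stack(fx, u))
      mask_r * rowSums(array(as.vector(I) * as.vector(Bx), dim(Bx)),
                       dims = 2L)
    }
    delta <- cg_solve(A_rho, -0.5 * g_rho * mask_r, options$inner_rho)
    stp <- 1
    for (try in 1:12) {
      cand <- pmax(rho + stp * delta, 0)
      pr <- forward_pred(cand, I)
      ot <- objective(cand, I, pr)
      if (ot$total < ob$total) {
        rho <- cand; pred <- pr; ob <- ot; accepted <- TRUE; break
      }
      stp <- stp / 2
    }

    ## ---- illumination block: CG in the free patterns V (last pattern
    ##      eliminated by the uniform-sum constraint) ----
    if (options$estimate_illumination && M >= 2L) {
      res <- pred - frames
      B <- conv$adjoint(binT_stack(res, u))
      gI <- 2 * array(as.vector(rho) * as.vector(B), dim(B)) +
        lam * tik_grad(I)
      gV <- gI[, , -M, drop = FALSE] -
        gI[, , rep(M, M - 1L), drop = FALSE]
      mask_v <- !(I[, , -M, drop = FALSE] <= 0 & gV > 0)
      lift <- function(dV) {                       # V-space -> full I-space
        dI <- array(0, dim(I))
        dI[, , -M] <- dV
        dI[, , M] <- -apply(dV, c(1L, 2L), sum)
        dI
      }
      A_V <- function(dV) {
        dI <- lift(dV * mask_v)
        fx <- bin_stack(conv$forward(array(as.vector(rho) * as.vector(dI),
                                           dim(dI))), u)
        Bx <- conv$adjoint(binT_stack(fx, u))
        aI <- 2 * array(as.vector(rho) * as.vector(Bx), dim(Bx)) +
          lam * tik_grad(dI)
        mask_v * (aI[, , -M, drop = FALSE] -
                    aI[, , rep(M, M - 1L), drop = FALSE])
      }
      dV <- cg_solve(A_V, -0.5 * gV * mask_v, options$inner_illum)
      dI <- lift(dV)
      stp <- 1
      for (try in 1:12) {
        candI <- project_I(I + stp * dI)
        pr <- forward_pred(rho, candI)
        ot <- objective(rho, candI, pr)
        if (ot$total < ob$total) {
          I <- candI; pred <- pr; ob <- ot; accepted <- TRUE; break
        }
        stp <- stp / 2
      }
    }

    cost_hist <- c(cost_hist, ob$total)
    n <- length(cost_hist)
    rel <- (cost_hist[n - 1L] - cost_hist[n]) / max(cost_hist[n - 1L],
                                                    .Machine$double.eps)
    if (rel < options$tol) { converged <- TRUE; break }
    if (!accepted) break
  }

  structure(list(rho = rho, illumination = I, cost = cost_hist,
                 data_cost = ob$data, converged = converged,
                 iterations = it, dx = stack$dx_c / u, options = options),
            class = "recon_result")
}

#' @export
print.recon_result <- function(x, ...) {
  cat(sprintf(
    "<recon_result> %d x %d px at %.3g nm, %d frames, %d iterations%s\n",
    nrow(x$rho), ncol(x$rho), x$dx, dim(x$illumination)[3L], x$iterations,
    if (x$converged) " (converged)" else ""))
  cat(sprintf("  objective %.4g -> %.4g (data term %.4g)\n",
              x$cost[1L], x$cost[length(x$cost)], x$data_cost))
  invisible(x)
}
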