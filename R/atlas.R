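# Spatial normalization to a common template grid and atlas averaging.
#
# Registration here is deliberately affine-only: the atlas logic, not the
# registration machinery, is the point. Dense nonlinear warps computed
# elsewhere can be imported (see `resample_to_template`'s `warp` hook).
# World convention: NIfTI sform, RAS+, transforms act on world coordinates;
# voxel (i,j,k) (1-based) maps to world A %*% (i-1, j-1, k-1, 1).

#' The standard template grid
#'
#' Fixed 91 x 109 x 91 voxel grid at 2 mm isotropic spacing with an MNI-style
#' RAS+ affine.
#'
#' @return A list of class `template_grid` with `shape`, `spacing`, `affine`.
#' @export
template_grid <- function() {
  affine <- rbind(c(-2, 0, 0, 90),
                  c(0, 2, 0, -126),
                  c(0, 0, 2, -72),
                  c(0, 0, 0, 1))
  structure(list(shape = c(91L, 109L, 91L), spacing = 2, affine = affine),
            class = "template_grid")
}

#' Affine transform between two named spaces
#'
#' @param matrix 4x4 homogeneous matrix acting on world coordinates
#'   (moving-world to fixed-world).
#' @param source,target space identifiers.
#' @return A list of class `affine_transform`.
#' @export
affine_transform <- function(matrix, source = "subject",
                             target = "template") {
  stopifnot(all(dim(matrix) == c(4, 4)))
  if (abs(det(matrix)) < 1e-12) stop("affine transform must be invertible")
  structure(list(matrix = matrix, source = source, target = target),
            class = "affine_transform")
}

#' Read/write world-space affine transforms as 4x4 text matrices
#'
#' @param transform an [affine_transform()].
#' @param path text file path.
#' @return `read_affine` returns an [affine_transform()].
#' @export
write_affine <- function(transform, path) {
  utils::write.table(transform$matrix, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_affine
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  affine_transform(m)
}

trilinear_sample <- function(src, coords) {
  dims <- dim(src)
  # snap near-integer coordinates so identity/integer shifts are exact
  snap <- abs(coords - round(coords)) < 1e-9
  coords[snap] <- round(coords[snap])
  lo <- floor(coords)
  fr <- coords - lo
  out <- rep(0, nrow(coords))
  inside <- lo[, 1] >= 1 & lo[, 1] + (fr[, 1] > 0) <= dims[1] &
            lo[, 2] >= 1 & lo[, 2] + (fr[, 2] > 0) <= dims[2] &
            lo[, 3] >= 1 & lo[, 3] + (fr[, 3] > 0) <= dims[3]
  idx <- function(i, j, k) ((k - 1) * dims[2] + (j - 1)) * dims[1] + i
  l <- lo[inside, , drop = FALSE]
  f <- fr[inside, , drop = FALSE]
  hx <- pmin(l[, 1] + 1, dims[1]); hy <- pmin(l[, 2] + 1, dims[2])
  hz <- pmin(l[, 3] + 1, dims[3])
  v <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3]) * src[idx(l[, 1], l[, 2], l[, 3])] +
       f[, 1] * (1 - f[, 2]) * (1 - f[, 3]) * src[idx(hx, l[, 2], l[, 3])] +
       (1 - f[, 1]) * f[, 2] * (1 - f[, 3]) * src[idx(l[, 1], hy, l[, 3])] +
       (1 - f[, 1]) * (1 - f[, 2]) * f[, 3] * src[idx(l[, 1], l[, 2], hz)] +
       f[, 1] * f[, 2] * (1 - f[, 3]) * src[idx(hx, hy, l[, 3])] +
       f[, 1] * (1 - f[, 2]) * f[, 3] * src[idx(hx, l[, 2], hz)] +
       (1 - f[, 1]) * f[, 2] * f[, 3] * src[idx(l[, 1], hy, hz)] +
       f[, 1] * f[, 2] * f[, 3] * src[idx(hx, hy, hz)]
  out[inside] <- v
  list(values = out, inside = inside)
}

resample_array <- function(src, src_affine, M, grid) {
  shape <- grid$shape
  n <- prod(shape)
  ijk <- arrayInd(seq_len(n), shape) - 1
  w <- t(grid$affine %*% t(cbind(ijk, 1)))
  wm <- t(solve(M) %*% t(w))
  pm <- t(solve(src_affine) %*% t(wm))[, 1:3, drop = FALSE] + 1
  s <- trilinear_sample(src, pm)
  list(data = array(s$values, shape), inside = array(s$inside, shape))
}

#' Resample a map through a transform chain onto a template grid
#'
#' All transforms in the chain are pre-multiplied into a single matrix and
#' applied once with trilinear interpolation (single-interpolation
#' contract). The mask travels through the same transform and is
#' re-binarized at 0.5.
#'
#' @param map a [property_maps()] (or a bare list with `mu`/`xi`/`mask`,
#'   `affine`).
#' @param transforms an [affine_transform()], a 4x4 matrix, or a list of
#'   either, ordered subject-to-template; they are composed by matrix
#'   multiplication (last applied first in world space).
#' @param grid a [template_grid()] or compatible list.
#' @return A [property_maps()] on the template grid.
#' @export
resample_to_template <- function(map, transforms, grid = template_grid()) {
  M <- compose_transforms(transforms)
  same_grid <- identical(dim(map$mask), as.integer(grid$shape)) &&
    max(abs(map$affine - grid$affine)) < 1e-12
  if (same_grid && max(abs(M - diag(4))) < 1e-12)
    return(property_maps(map$mu, map$xi, map$mask, grid$spacing, grid$affine,
                         map$provenance %||% list()))
  mu <- resample_array(map$mu, map$affine, M, grid)
  xi <- resample_array(map$xi, map$affine, M, grid)
  msk <- resample_array(map$mask * 1, map$affine, M, grid)
  mask_new <- msk$data >= 0.5 & msk$inside
  if (!any(mask_new))
    stop("output grid lies entirely outside the source support")
  property_maps(mu$data, xi$data, mask_new, grid$spacing, grid$affine,
                map$provenance %||% list())
}

compose_transforms <- function(transforms) {
  as_mat <- function(t) {
    if (inherits(t, "affine_transform")) t$matrix else t
  }
  if (is.list(transforms) && !inherits(transforms, "affine_transform"))
    Reduce(`%*%`, lapply(transforms, as_mat))
  else as_mat(transforms)
}

params_to_affine <- function(p, center) {
  t <- p[1:3]
  r <- p[4:6] * pi / 180
  s <- exp(p[7:9])
  sh <- p[10:12]
  Rx <- rbind(c(1, 0, 0), c(0, cos(r[1]), -sin(r[1])),
              c(0, sin(r[1]), cos(r[1])))
  Ry <- rbind(c(cos(r[2]), 0, sin(r[2])), c(0, 1, 0),
              c(-sin(r[2]), 0, cos(r[2])))
  Rz <- rbind(c(cos(r[3]), -sin(r[3]), 0), c(sin(r[3]), cos(r[3]), 0),
              c(0, 0, 1))
  Sh <- rbind(c(1, sh[1], sh[2]), c(0, 1, sh[3]), c(0, 0, 1))
  A <- Rz %*% Ry %*% Rx %*% Sh %*% diag(s)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- center - A %*% center + t
  M
}

nmi_metric <- function(a, b, nbins = 32) {
  sel <- is.finite(a) & is.finite(b)
  a <- a[sel]; b <- b[sel]
  if (length(a) < 100) return(0)
  cut1 <- findInterval(a, seq(min(a), max(a), length.out = nbins + 1),
                       all.inside = TRUE)
  cut2 <- findInterval(b, seq(min(b), max(b), length.out = nbins + 1),
                       all.inside = TRUE)
  joint <- tabulate((cut2 - 1) * nbins + cut1, nbins * nbins)
  pj <- joint / sum(joint)
  px <- rowSums(matrix(pj, nbins))
  py <- colSums(matrix(pj, nbins))
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  (H(px) + H(py)) / max(H(pj), 1e-12)
}

com_world <- function(vol, affine) {
  w <- vol$data - min(vol$data)
  idx <- arrayInd(seq_along(w), dim(vol$data)) - 1
  cw <- colSums(idx * as.vector(w)) / sum(w)
  (affine %*% c(cw, 1))[1:3]
}

#' Estimate a world-space affine transform by similarity maximization
#'
#' Maximizes normalized mutual information (32-bin histograms) between the
#' fixed volume and the moving volume resampled through the candidate
#' transform. Initialization is a centre-of-mass translation; refinement is
#' derivative-free (Nelder-Mead), first over the 6 rigid parameters and then
#' over all 12 affine parameters (translation mm, rotation deg, log-scales,
#' shears). Parameters ending on the search-box boundary raise an error with
#' diagnostics.
#'
#' @param moving,fixed lists with `data` (3-D array) and `affine` (4x4).
#' @param nbins histogram bins for the metric.
#' @param maxit Nelder-Mead iteration budget per stage.
#' @return An [affine_transform()] with attributes `metric` (achieved NMI)
#'   and `params`.
#' @export
estimate_affine <- function(moving, fixed, nbins = 32, maxit = 600) {
  grid <- list(shape = dim(fixed$data), spacing = NA, affine = fixed$affine)
  center <- com_world(fixed, fixed$affine)
  t0 <- center - com_world(moving, moving$affine)
  box <- c(rep(60, 3), rep(50, 3), rep(log(1.6), 3), rep(0.4, 3))
  neg_metric <- function(p12) {
    if (any(abs(p12 - c(t0, rep(0, 9))) > box * 1.05)) return(1e6)
    M <- params_to_affine(p12, center)
    r <- resample_array(moving$data, moving$affine, M, grid)
    v <- r$data
    v[!r$inside] <- NA
    -nmi_metric(v[r$inside], fixed$data[r$inside], nbins)
  }
  p <- c(t0, rep(0, 9))
  obj_rigid <- function(p6) neg_metric(c(p6, p[7:12]))
  o1 <- stats::optim(p[1:6], obj_rigid, method = "Nelder-Mead",
                     control = list(maxit = maxit,
                                    parscale = c(rep(2, 3), rep(2, 3))))
  p[1:6] <- o1$par
  o2 <- stats::optim(p, neg_metric, method = "Nelder-Mead",
                     control = list(maxit = 2 * maxit,
                                    parscale = c(rep(2, 6), rep(0.05, 6))))
  p <- o2$par
  rel <- abs(p - c(t0, rep(0, 9))) / box
  if (any(rel > 0.99))
    stop("affine estimation hit the search-box boundary at parameter(s) ",
         paste(which(rel > 0.99), collapse = ", "),
         " (params: ", paste(signif(p, 3), collapse = ", "), ")")
  tr <- affine_transform(params_to_affine(p, center))
  attr(tr, "metric") <- -o2$value
  attr(tr, "params") <- p
  tr
}

#' Average template-space property maps into an atlas
#'
#' Voxelwise mean over the subjects whose (resampled) mask covers each
#' voxel; emits the voxelwise between-subject SD and the coverage count.
#' With `coverage_mode = "template"` only voxels covered by every subject
#' are retained; with `"subject"` (default) any covered voxel is averaged
#' over its covering subjects.
#'
#' @param maps list of [property_maps()] on a common grid.
#' @param coverage_mode "subject" or "template".
#' @return A list of class `mre_atlas`: `mu_mean`, `xi_mean`, `mu_sd`,
#'   `xi_sd`, `coverage`, `mask`, `n_subjects`, `spacing`, `affine`, `shape`.
#' @export
build_atlas <- function(maps, coverage_mode = c("subject", "template")) {
  coverage_mode <- match.arg(coverage_mode)
  stopifnot(length(maps) >= 1)
  dims <- dim(maps[[1]]$mask)
  for (m in maps)
    if (!identical(dim(m$mask), dims)) stop("property map shape mismatch")
  acc <- function(get) {
    s1 <- array(0, dims); s2 <- array(0, dims)
    for (m in maps) {
      v <- get(m) * m$mask
      s1 <- s1 + v
      s2 <- s2 + v^2
    }
    list(s1 = s1, s2 = s2)
  }
  cov <- array(0L, dims)
  for (m in maps) cov <- cov + m$mask
  mask <- if (coverage_mode == "template") cov == length(maps) else cov > 0
  mu <- acc(function(m) m$mu)
  xi <- acc(function(m) m$xi)
  safe_div <- function(a) { out <- array(0, dims); out[mask] <- a[mask] / cov[mask]; out }
  mu_mean <- safe_div(mu$s1)
  xi_mean <- safe_div(xi$s1)
  sd_of <- function(s, mean) {
    out <- array(0, dims)
    ok <- mask & cov >= 2
    v <- (s$s2[ok] - cov[ok] * mean[ok]^2) / (cov[ok] - 1)
    out[ok] <- sqrt(pmax(v, 0))
    out
  }
  structure(list(mu_mean = mu_mean, xi_mean = xi_mean,
                 mu_sd = sd_of(mu, mu_mean), xi_sd = sd_of(xi, xi_mean),
                 coverage = cov, mask = mask, n_subjects = length(maps),
                 spacing = maps[[1]]$spacing, affine = maps[[1]]$affine,
                 shape = dims),
            class = "mre_atlas")
}

#' @export
print.mre_atlas <- function(x, ...) {
  cat("<mre_atlas> ", paste(x$shape, collapse = "x"), " @ ", x$spacing,
      " mm, N = ", x$n_subjects, "\n", sep = "")
  cat(sprintf("  mask-mean mu = %.3f kPa, xi = %.4f\n",
              mean(x$mu_mean[x$mask]), mean(x$xi_mean[x$mask])))
  invisible(x)
}
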