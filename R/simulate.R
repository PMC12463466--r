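#' Generate contiguous spatial domains on a lattice
#'
#' Lays out a \code{width} x \code{height} square lattice of spots and
#' assigns each spot to one of \code{K} contiguous domains:
#' \code{"stripes"} cuts K horizontal bands of near-equal size,
#' \code{"quadrants"} tiles the rectangle with an approximately square
#' arrangement of blocks, and \code{"file"} uses labels supplied verbatim
#' via \code{labels}. Every domain is non-empty and edge-connected under
#' 4-adjacency.
#'
#' @param width,height lattice dimensions.
#' @param K number of domains.
#' @param pattern \code{"stripes"}, \code{"quadrants"} or \code{"file"}.
#' @param labels length-(width*height) label vector for \code{"file"}.
#' @return list with \code{coords} (n x 2 matrix, row-major lattice order)
#'   and \code{z} (integer domain labels in 1..K).
#' @export
generateDomains <- function(width, height, K,
                            pattern = c("stripes", "quadrants", "file"),
                            labels = NULL) {
  pattern <- match.arg(pattern)
  n <- width * height
  coords <- cbind(
    x = rep(seq_len(width), times = height),
    y = rep(seq_len(height), each = width)
  )
  rownames(coords) <- paste0("spot", seq_len(n))
  if (pattern == "file") {
    if (is.null(labels) || length(labels) != n) {
      stop("pattern 'file' requires one label per lattice spot")
    }
    z <- as.integer(labels)
    if (min(z) < 1L || max(z) > K) stop("labels out of 1..K")
  } else if (pattern == "stripes") {
    if (K > height) stop("K exceeds the number of lattice rows")
    band <- if (K == 1L) {
      rep(1L, height)
    } else {
      as.integer(cut(seq_len(height), K, labels = FALSE))
    }
    z <- band[coords[, "y"]]
  } else {
    nx <- ceiling(sqrt(K))
    ny <- ceiling(K / nx)
    if (nx > width || ny > height) stop("K exceeds representable quadrants")
    bx <- as.integer(cut(seq_len(width), nx, labels = FALSE))
    by <- as.integer(cut(seq_len(height), ny, labels = FALSE))
    tile <- (by[coords[, "y"]] - 1L) * nx + bx[coords[, "x"]]
    # collapse spare tiles (when nx*ny > K) into the last domain
    z <- pmin(tile, K)
  }
  if (length(unique(z)) != K) stop("some domains are empty")
  list(coords = coords, z = as.integer(z))
}

#' Simulate a spatial transcriptomics dataset with ground truth
#'
#' Emulates the study design used to benchmark the model: spots on a
#' square lattice partitioned into K contiguous domains; each gene is a
#' non-discriminating gene (non-DG) with probability \code{pi0}, otherwise
#' uniformly assigned to one of R groups; block means
#' \eqn{\mu_{rk} = \mu_{base} + (k-1)\Delta + (r-1)\Delta}; per-gene null
#' means \eqn{\mu_{0j} \sim \mathrm{Unif}(2, 6)}; multiplicative spot and
#' gene factors \eqn{s_i, g_j \sim \mathrm{Unif}(0.5, 1.5)}; mean-level
#' noise \eqn{\epsilon_{ij} \sim \mathrm{Unif}(-w, w)}; and Poisson counts
#' \eqn{y_{ji} \sim \mathrm{Poi}\{s_i g_j (\mu + \epsilon_{ij})\}}, or
#' Negative Binomial counts with the same mean and per-gene dispersion
#' \eqn{\psi_j \sim \mathrm{Exp}(0.1)} (variance \eqn{m + m^2/\psi_j}) in
#' the misspecification variant.
#'
#' @param width,height lattice size (default 10 x 10).
#' @param p number of genes.
#' @param K,R numbers of domains and gene groups.
#' @param pi0 expected proportion of non-DGs in [0, 1).
#' @param delta signal strength between adjacent blocks.
#' @param mu_base baseline block mean (default 4).
#' @param mu0_range range of the per-gene null means.
#' @param factor_range range of the spot/gene scaling factors.
#' @param noise_half_width half-width w of the mean-level noise.
#' @param family \code{"poisson"} or \code{"negative-binomial"}.
#' @param psi_rate rate of the exponential dispersion draw (NB family).
#' @param pattern domain pattern, see [generateDomains()].
#' @param labels explicit domain labels for \code{pattern = "file"}.
#' @param seed integer seed; the dataset is fully reproducible from it.
#' @return list with \code{counts} (p x n integer matrix), \code{coords},
#'   \code{z_true}, \code{rho_true}, \code{s_true}, \code{g_true},
#'   \code{mu_true} (R x K), \code{mu0_true} (per-gene, NA for DGs),
#'   \code{psi_true} (NB family only) and \code{config}.
#' @export
simulateSRT <- function(width = 10L, height = 10L, p = 500L, K = 4L, R = 3L,
                        pi0 = 0.2, delta = 1, mu_base = 4,
                        mu0_range = c(2, 6), factor_range = c(0.5, 1.5),
                        noise_half_width = 0.1,
                        family = c("poisson", "negative-binomial"),
                        psi_rate = 0.1, pattern = "stripes", labels = NULL,
                        seed = 1L) {
  family <- match.arg(family)
  stopifnot(
    pi0 >= 0, pi0 < 1, delta > 0, mu0_range[1] <= mu0_range[2],
    factor_range[1] <= factor_range[2], noise_half_width >= 0
  )
  dom <- generateDomains(width, height, K, pattern = pattern, labels = labels)
  n <- nrow(dom$coords)
  set.seed(seed)
  z <- dom$z
  rho <- ifelse(
    runif(p) < pi0, 0L,
    sample.int(R, p, replace = TRUE)
  )
  rho <- as.integer(rho)
  s <- runif(n, factor_range[1], factor_range[2])
  g <- runif(p, factor_range[1], factor_range[2])
  mu <- outer(seq_len(R) - 1L, seq_len(K) - 1L, function(r, k) {
    mu_base + k * delta + r * delta
  })
  mu0 <- rep(NA_real_, p)
  mu0[rho == 0L] <- runif(sum(rho == 0L), mu0_range[1], mu0_range[2])
  base <- matrix(NA_real_, p, n)
  dg <- rho > 0L
  if (any(dg)) base[dg, ] <- mu[cbind(rep(rho[dg], n), rep(z, each = sum(dg)))]
  if (any(!dg)) base[!dg, ] <- mu0[!dg]
  eps <- matrix(
    runif(p * n, -noise_half_width, noise_half_width), p, n
  )
  rate <- sweep(sweep(pmax(base + eps, 1e-6), 1L, g, "*"), 2L, s, "*")
  psi <- NULL
  if (family == "poisson") {
    counts <- matrix(rpois(p * n, rate), p, n)
  } else {
    psi <- rexp(p, psi_rate)
    counts <- matrix(
      rnbinom(p * n, size = rep(psi, n), mu = rate), p, n
    )
  }
  dimnames(counts) <- list(
    paste0("gene", seq_len(p)), rownames(dom$coords)
  )
  list(
    counts = counts, coords = dom$coords, z_true = z, rho_true = rho,
    s_true = s, g_true = g, mu_true = mu, mu0_true = mu0, psi_true = psi,
    config = list(
      width = width, height = height, p = p, K = K, R = R, pi0 = pi0,
      delta = delta, mu_base = mu_base, mu0_range = mu0_range,
      factor_range = factor_range, noise_half_width = noise_half_width,
      family = family, psi_rate = psi_rate, pattern = pattern, seed = seed
    )
  )
}

#' Benchmark scenario grid
#'
#' The Cartesian product of gene counts, non-DG proportions and signal
#' strengths used in the benchmarking design -- by default
#' p in \{500, 1000\} x pi0 in \{0, 0.2, 0.4, 0.6, 0.8\} x
#' delta in \{0.5, 1, 1.5\}, i.e. 30 scenarios -- each replicated
#' \code{nReps} times with replicate seeds 1..nReps.
#'
#' @param p,pi0,delta scenario axes.
#' @param nReps replicates per scenario (default 50).
#' @return a data.frame with one row per (scenario, replicate) and columns
#'   \code{scenario}, \code{p}, \code{pi0}, \code{delta}, \code{rep},
#'   \code{seed}.
#' @export
scenarioGrid <- function(p = c(500L, 1000L), pi0 = seq(0, 0.8, by = 0.2),
                         delta = c(0.5, 1, 1.5), nReps = 50L) {
  sc <- expand.grid(p = p, pi0 = pi0, delta = delta)
  sc$scenario <- seq_len(nrow(sc))
  out <- merge(sc, data.frame(rep = seq_len(nReps)))
  out <- out[order(out$scenario, out$rep), ]
  out$seed <- out$rep
  rownames(out) <- NULL
  out[, c("scenario", "p", "pi0", "delta", "rep", "seed")]
}

#' Write a simulated dataset to a directory
#'
#' Writes the counts (\code{counts.csv}), coordinates (\code{coords.csv}),
#' truth files (\code{z_true.csv}, \code{rho_true.csv},
#' \code{factors.csv}, \code{mu_true.csv}) and the resolved configuration
#' (\code{config.json}).
#'
#' @param sim output of [simulateSRT()].
#' @param dir output directory (created if missing).
#' @param format counts format passed to [writeCounts()].
#' @return \code{dir}, invisibly.
#' @export
writeSimulation <- function(sim, dir, format = "csv") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ext <- if (format == "mtx") "mtx" else format
  writeCounts(sim$counts, file.path(dir, paste0("counts.", ext)), format)
  write.csv(
    data.frame(
      spot_id = rownames(sim$coords), x = sim$coords[, 1],
      y = sim$coords[, 2]
    ),
    file.path(dir, "coords.csv"),
    row.names = FALSE
  )
  write.csv(
    data.frame(spot_id = rownames(sim$coords), domain = sim$z_true),
    file.path(dir, "z_true.csv"),
    row.names = FALSE
  )
  write.csv(
    data.frame(gene_id = rownames(sim$counts), group = sim$rho_true),
    file.path(dir, "rho_true.csv"),
    row.names = FALSE
  )
  write.csv(
    data.frame(
      id = c(rownames(sim$coords), rownames(sim$counts)),
      kind = c(
        rep("spot", length(sim$s_true)),
        rep("gene", length(sim$g_true))
      ),
      factor = c(sim$s_true, sim$g_true)
    ),
    file.path(dir, "factors.csv"),
    row.names = FALSE
  )
  write.csv(sim$mu_true, file.path(dir, "mu_true.csv"), row.names = FALSE)
  jsonlite::write_json(sim$config, file.path(dir, "config.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
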