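#' Trajectory container
#'
#' Timestamped particle positions with a periodic box, a particle-to-chain
#' map, per-particle partial charges and masses. Positions may be stored
#' wrapped into the box; analyses unwrap them as needed.
#'
#' @param times frame times, ns, uniform spacing.
#' @param coords array n_frames x n_atoms x 3, Angstrom.
#' @param box periodic box edge lengths, Angstrom (length 3 or scalar).
#' @param chain_id integer chain index per atom.
#' @param species optional chain species labels (per chain).
#' @param charge per-atom partial charges, e (optional).
#' @param mass per-atom masses, amu (default 1).
#' @param wrapped are coordinates wrapped into the box?
#' @param meta list of provenance (generator truth parameters etc.).
#' @export
trajectory <- function(times, coords, box, chain_id, species = NULL,
                       charge = NULL, mass = NULL, wrapped = TRUE,
                       meta = list()) {
  coords <- as.array(coords)
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L)
  n_frames <- dim(coords)[1]
  n_atoms <- dim(coords)[2]
  if (length(times) != n_frames) stop("times length must match frame count")
  if (n_frames > 2L) check_uniform_grid(times)
  box <- rep_len(box, 3L)
  if (any(box <= 0)) stop("box edges must be > 0")
  if (length(chain_id) != n_atoms)
    stop("chain map must cover every particle")
  if (!all(is.finite(coords))) stop("positions must be finite")
  if (is.null(mass)) mass <- rep(1, n_atoms)
  structure(list(times = times, coords = coords, box = box,
                 chain_id = as.integer(chain_id), species = species,
                 charge = charge, mass = mass, wrapped = wrapped,
                 meta = meta),
            class = "trajectory")
}

#' Unwrap periodic coordinates
#'
#' Removes box jumps by accumulating minimum-image displacements frame to
#' frame, per atom.
#'
#' @param traj a \code{trajectory}.
#' @return the trajectory with continuous coordinates (\code{wrapped = FALSE}).
#' @export
unwrap_trajectory <- function(traj) {
  if (!traj$wrapped) return(traj)
  if (is.null(traj$box)) stop("unwrapping error: wrapped coordinates need a box")
  co <- traj$coords
  n <- dim(co)[1]
  if (n > 1) {
    for (d in 1:3) {
      L <- traj$box[d]
      x <- co[, , d, drop = FALSE]
      dim(x) <- dim(co)[1:2]
      dx <- diff(x)
      dx <- dx - L * round(dx / L)
      cs <- apply(dx, 2, cumsum)
      if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
      co[, , d] <- rbind(x[1, , drop = FALSE],
                         x[rep(1, n - 1), , drop = FALSE] + cs)
    }
  }
  traj$coords <- co
  traj$wrapped <- FALSE
  traj
}

chain_com <- function(traj, chains = NULL) {
  traj <- unwrap_trajectory(traj)
  ids <- sort(unique(traj$chain_id))
  if (!is.null(chains)) ids <- intersect(ids, chains)
  if (length(ids) == 0L) stop("selection is empty")
  n <- dim(traj$coords)[1]
  out <- array(0, c(n, length(ids), 3))
  for (k in seq_along(ids)) {
    sel <- which(traj$chain_id == ids[k])
    m <- traj$mass[sel]
    for (d in 1:3) {
      x <- traj$coords[, sel, d, drop = FALSE]
      dim(x) <- c(n, length(sel))
      out[, k, d] <- as.vector(x %*% m) / sum(m)
    }
  }
  dimnames(out) <- list(NULL, as.character(ids), NULL)
  out
}

# FFT-based time-origin-averaged MSD of one scalar series
msd_1d <- function(x) {
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  Fx <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Fx * Conj(Fx), inverse = TRUE))[1:n] / nfft
  sq <- x^2
  msd <- numeric(n)
  sumsq <- 2 * sum(sq)
  for (m in 1:(n - 1)) {
    sumsq <- sumsq - sq[m] - sq[n + 1 - m]
    msd[m + 1] <- sumsq / (n - m) - 2 * ac[m + 1] / (n - m)
  }
  msd
}

#' Mean squared displacement of chain centres of mass
#'
#' Time-origin-averaged MSD on unwrapped coordinates, per chain, plus the
#' unweighted ensemble mean across chains.
#'
#' @param traj a \code{trajectory} (>= 10 frames).
#' @param selection optional vector of chain ids.
#' @return an \code{msd_result}: lag times (ns), \code{msd} (ensemble mean,
#'   Angstrom^2) and \code{per_chain} matrix (lags x chains).
#' @export
compute_msd <- function(traj, selection = NULL) {
  if (dim(traj$coords)[1] < 10L) stop("at least 10 frames required")
  com <- chain_com(traj, selection)
  n <- dim(com)[1]
  nc <- dim(com)[2]
  per <- matrix(0, n, nc, dimnames = list(NULL, dimnames(com)[[2]]))
  for (k in seq_len(nc))
    for (d in 1:3) per[, k] <- per[, k] + msd_1d(com[, k, d])
  dt <- traj$times[2] - traj$times[1]
  structure(list(lags = (seq_len(n) - 1) * dt,
                 msd = rowMeans(per), per_chain = per),
            class = "msd_result")
}

#' Translational diffusion coefficient from an MSD window
#'
#' Least-squares slope of the ensemble MSD over the lag window, divided
#' by 6. The default window is the 0.3-5 ns regime probed experimentally.
#'
#' @param msd an \code{msd_result}.
#' @param window c(min, max) lag window, ns.
#' @return list with D (Angstrom^2/ns), D_se, slope, intercept.
#' @export
fit_diffusion <- function(msd, window = c(0.3, 5)) {
  sel <- msd$lags >= window[1] & msd$lags <= window[2]
  if (sum(sel) < 2L)
    stop("range error: fewer than 2 lag points inside the window")
  if (window[1] < 0 || window[2] > max(msd$lags))
    stop("range error: window outside the available lag range")
  fit <- stats::lm(y ~ x, data = data.frame(x = msd$lags[sel], y = msd$msd[sel]))
  cf <- stats::coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  list(D = unname(cf[2]) / 6, D_se = unname(se[2]) / 6,
       slope = unname(cf[2]), intercept = unname(cf[1]))
}

#' Hydrodynamic finite-size correction for periodic boxes
#'
#' Adds the cubic-lattice self-interaction term
#' kB*T*xi/(6*pi*eta*L), xi = 2.837297, to a diffusion coefficient
#' computed under periodic boundary conditions.
#'
#' @param D_pbc diffusion coefficient from the periodic simulation,
#'   Angstrom^2/ns.
#' @param T temperature, K.
#' @param eta shear viscosity, mPa*s.
#' @param box_edge cubic box edge, Angstrom.
#' @return corrected D, Angstrom^2/ns.
#' @export
pbc_correction <- function(D_pbc, T, eta, box_edge) {
  if (T <= 0 || eta <= 0 || box_edge <= 0)
    stop("invalid parameter: T, eta and box_edge must be > 0")
  corr_SI <- pt_constants$kB_SI * T * pt_constants$xi_cubic /
    (6 * pi * eta * 1e-3 * box_edge * 1e-10)   # m^2/s
  D_pbc + corr_SI * 1e11                       # -> Angstrom^2/ns
}

principal_axes <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  S <- crossprod(Xc) / nrow(Xc)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2] < 1e-10 * max(e$values[1], 1e-300))
    stop("geometry error: chain is collinear or degenerate")
  e$vectors
}

#' Rotational diffusion coefficient of a chain
#'
#' Second-rank orientational autocorrelation C2(t) of the chain's
#' principal axes (sign-continuous across frames), averaged over the three
#' axes and all time origins; a single-exponential fit gives tau2 and
#' D_r = 1/(6 tau2).
#'
#' @param traj a \code{trajectory}.
#' @param chain chain id (default: first chain).
#' @param max_lag_frac fraction of the trajectory length used as maximum
#'   lag for the correlation (default 0.5).
#' @return list with D_r (1/ns), tau2 (ns), lags, C2.
#' @export
rotational_diffusion <- function(traj, chain = NULL, max_lag_frac = 0.5) {
  traj <- unwrap_trajectory(traj)
  if (is.null(chain)) chain <- sort(unique(traj$chain_id))[1]
  sel <- which(traj$chain_id == chain)
  if (length(sel) < 3L) stop("geometry error: chain needs >= 3 particles")
  n <- dim(traj$coords)[1]
  axes <- array(0, c(n, 3, 3))   # frame x axis x component
  prev <- NULL
  for (t in seq_len(n)) {
    V <- principal_axes(traj$coords[t, sel, ])
    if (!is.null(prev))
      for (a in 1:3) if (sum(V[, a] * prev[, a]) < 0) V[, a] <- -V[, a]
    axes[t, , ] <- t(V)
    prev <- V
  }
  nlag <- max(2L, floor(n * max_lag_frac))
  C2 <- numeric(nlag)
  C2[1] <- 1
  for (m in 1:(nlag - 1)) {
    acc <- 0
    for (a in 1:3) {
      dots <- rowSums(axes[1:(n - m), a, ] * axes[(1 + m):n, a, ])
      acc <- acc + mean(1.5 * dots^2 - 0.5)
    }
    C2[m + 1] <- acc / 3
  }
  dt <- traj$times[2] - traj$times[1]
  lags <- (seq_len(nlag) - 1) * dt
  if (all(C2 > 0.999)) {
    return(list(D_r = 0, tau2 = Inf, lags = lags, C2 = C2))
  }
  # fit the initial decay only: long lags are dominated by sampling noise
  below <- which(C2 < 0.2)
  last <- if (length(below)) max(below[1] - 1L, 3L) else nlag
  keep <- seq_len(min(last, nlag))[-1]
  keep <- keep[C2[keep] > 0]
  fit <- stats::lm(log(C2[keep]) ~ lags[keep] + 0)
  tau2 <- -1 / unname(stats::coef(fit)[1])
  list(D_r = 1 / (6 * tau2), tau2 = tau2, lags = lags, C2 = C2)
}

sph_bessel <- function(l, x) {
  # j_l(x) via half-integer Bessel J; j_0(0)=1, j_l(0)=0 for l>0
  out <- numeric(length(x))
  z <- x > 1e-12
  if (any(z)) out[z] <- sqrt(pi / (2 * x[z])) * besselJ(x[z], l + 0.5)
  if (any(!z)) out[!z] <- if (l == 0) 1 else 0
  out
}

#' Apparent global diffusion coefficient of a rigid body
#'
#' Recombines translational and rotational diffusion into the apparent
#' coefficient a quasi-elastic experiment reports: the rigid-body
#' incoherent intermediate scattering function
#' I(q,t) = exp(-q^2 D_t t) * sum_l S_l(q) exp(-l(l+1) D_r t), with
#' S_l(q) = (2l+1) <j_l(q r_j)^2> over the scattering sites, is fitted by
#' a single exponential exp(-q^2 D_app(q) t) over the observation window;
#' the apparent coefficient is the mean of D_app(q) over the instrument's
#' q range.
#'
#' @param D_t translational diffusion coefficient, Angstrom^2/ns.
#' @param D_r rotational diffusion coefficient, 1/ns.
#' @param site_radii distances of scattering sites from the centre of
#'   mass, Angstrom.
#' @param q_values 1/Angstrom.
#' @param t_window observation window, ns (default the 0.3-5 ns regime).
#' @param l_max expansion truncation order.
#' @param n_t time samples used in the fit.
#' @return list with D_G_app, per-q D_app, and the truncated weight.
#' @export
apparent_DG <- function(D_t, D_r, site_radii, q_values,
                        t_window = c(0.3, 5), l_max = 60L, n_t = 40L) {
  stopifnot(D_t >= 0, D_r >= 0, all(site_radii >= 0), all(q_values > 0))
  tg <- seq(t_window[1], t_window[2], length.out = n_t)
  D_app <- numeric(length(q_values))
  max_tail <- 0
  for (i in seq_along(q_values)) {
    q <- q_values[i]
    S_l <- vapply(0:l_max, function(l)
      (2 * l + 1) * mean(sph_bessel(l, q * site_radii)^2), numeric(1))
    tail_w <- 1 - sum(S_l)
    max_tail <- max(max_tail, tail_w)
    ls <- 0:l_max
    I_qt <- exp(-q^2 * D_t * tg) *
      as.vector(exp(-outer(tg, ls * (ls + 1) * D_r)) %*% S_l)
    fit <- stats::lm(log(I_qt) ~ tg)
    D_app[i] <- -unname(stats::coef(fit)[2]) / q^2
  }
  if (max_tail > 1e-4)
    warning("truncation: spherical-harmonic tail weight ", signif(max_tail, 3))
  list(D_G_app = mean(D_app), D_app = D_app, q_values = q_values,
       tail_weight = max_tail)
}

# time-origin-averaged autocovariance (biased normalisation 1/(n-m)) via FFT
autocov_series <- function(x, nlag) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  Fx <- stats::fft(c(x, rep(0, nfft - n)))
  ac <- Re(stats::fft(Fx * Conj(Fx), inverse = TRUE))[1:nlag] / nfft
  ac / (n - (seq_len(nlag) - 1))
}

#' Green-Kubo shear viscosity from pressure fluctuations
#'
#' eta = (V/(kB T)) * integral_0^cutoff <P(0)P(t)> dt, with the
#' autocorrelation averaged over the supplied off-diagonal pressure
#' components and integrated by the trapezoidal rule. Unit convention:
#' pressure in bar, V in Angstrom^3, time in ns, output in mPa*s.
#'
#' @param pressure_series data.frame with a \code{time} column (ns) and one
#'   column per tensor component (bar).
#' @param T temperature, K.
#' @param V volume, Angstrom^3.
#' @param cutoff upper integration limit, ns.
#' @return a \code{viscosity_result}: eta (mPa*s), the running integral
#'   curve, and the cutoff.
#' @export
green_kubo_viscosity <- function(pressure_series, T, V, cutoff) {
  stopifnot(is.data.frame(pressure_series), "time" %in% names(pressure_series))
  comp <- setdiff(names(pressure_series), "time")
  if (length(comp) < 2L) stop("at least 2 pressure components required")
  tm <- pressure_series$time
  dt <- tm[2] - tm[1]
  if (cutoff > max(tm) - min(tm)) stop("range error: cutoff exceeds the series")
  nlag <- min(floor(cutoff / dt) + 1L, length(tm))
  ac <- rowMeans(vapply(comp, function(cn)
    autocov_series(pressure_series[[cn]], nlag), numeric(nlag)))
  lags <- (seq_len(nlag) - 1) * dt
  # trapezoidal running integral
  run <- c(0, cumsum((ac[-1] + ac[-nlag]) / 2 * dt))
  unit <- 1e-26 * V / (pt_constants$kB_SI * T)   # bar^2*ns*A^3 -> mPa*s
  structure(list(eta = unit * run[nlag], running = data.frame(
                   t = lags, eta = unit * run),
                 acf = ac, cutoff = cutoff),
            class = "viscosity_result")
}

# ---- contacts and clusters ---------------------------------------------

min_image_dist2 <- function(dx, box) {
  for (d in 1:3) dx[, d] <- dx[, d] - box[d] * round(dx[, d] / box[d])
  rowSums(dx^2)
}

# candidate atom pairs from a periodic cell list (exact: every pair within
# the cutoff appears; duplicates removed)
cell_list_pairs <- function(X, box, cutoff) {
  n <- nrow(X)
  nc <- pmax(1L, pmin(floor(box / cutoff), 12L))
  if (any(nc < 3L)) {
    # too few cells for a meaningful decomposition: all pairs
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    return(idx)
  }
  cell <- matrix(0L, n, 3)
  for (d in 1:3) {
    frac <- (X[, d] / box[d]) %% 1
    cell[, d] <- pmin(floor(frac * nc[d]), nc[d] - 1L)
  }
  lin <- cell[, 1] + nc[1] * (cell[, 2] + nc[2] * cell[, 3]) + 1L
  by_cell <- split(seq_len(n), lin)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- vector("list", 0); out_j <- vector("list", 0)
  cells <- unique(cell)
  for (r in seq_len(nrow(cells))) {
    c0 <- cells[r, ]
    id0 <- c0[1] + nc[1] * (c0[2] + nc[2] * c0[3]) + 1L
    a0 <- by_cell[[as.character(id0)]]
    for (o in seq_len(nrow(offs))) {
      cn <- (c0 + offs[o, ]) %% nc
      idn <- cn[1] + nc[1] * (cn[2] + nc[2] * cn[3]) + 1L
      # with >= 3 cells per dimension each neighbour is a distinct cell, so
      # visiting each (cell, neighbour >= cell) pair once covers every pair
      if (idn < id0) next
      an <- by_cell[[as.character(idn)]]
      if (is.null(an)) next
      if (idn == id0) {
        if (length(a0) < 2L) next
        pr <- utils::combn(a0, 2L)
        ii <- pr[1, ]; jj <- pr[2, ]
      } else {
        g <- expand.grid(a0, an)
        ii <- pmin(g[, 1], g[, 2]); jj <- pmax(g[, 1], g[, 2])
      }
      out_i[[length(out_i) + 1L]] <- ii
      out_j[[length(out_j) + 1L]] <- jj
    }
  }
  cbind(row = unlist(out_i), col = unlist(out_j))
}

#' Inter-chain contact statistics of a single frame
#'
#' Atom pairs belonging to different chains and closer than the cutoff
#' (minimum-image convention) are contacts; a chain pair sharing at least
#' one contact are interaction partners. Each contact is classed by the
#' partial charges of its atoms: an atom is "hydrophobic" (Pho) when
#' |charge| < \code{charge_threshold}, "hydrophilic" (Phi) otherwise.
#'
#' @param traj a \code{trajectory} with charges.
#' @param frame frame index (default 1).
#' @param cutoff contact distance, Angstrom (default 4).
#' @param charge_threshold e (default 0.2).
#' @param method "cell_list" (default) or "brute_force" (the O(N^2)
#'   reference path).
#' @return a \code{contact_stats}: per-chain partner and contact counts,
#'   class tallies, and the contact pair table.
#' @export
contact_stats <- function(traj, frame = 1L, cutoff = 4, charge_threshold = 0.2,
                          method = c("cell_list", "brute_force")) {
  method <- match.arg(method)
  if (cutoff <= 0) stop("invalid parameter: cutoff must be > 0")
  if (is.null(traj$charge))
    stop("missing attribute: partial charges are required")
  X <- traj$coords[frame, , ]
  box <- traj$box
  chain <- traj$chain_id
  n <- nrow(X)
  pairs <- if (method == "cell_list") cell_list_pairs(X, box, cutoff)
           else which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- pairs[, 1]; j <- pairs[, 2]
  keep <- chain[i] != chain[j]
  i <- i[keep]; j <- j[keep]
  d2 <- min_image_dist2(X[i, , drop = FALSE] - X[j, , drop = FALSE], box)
  hit <- d2 <= cutoff^2
  i <- i[hit]; j <- j[hit]
  pho_i <- abs(traj$charge[i]) < charge_threshold
  pho_j <- abs(traj$charge[j]) < charge_threshold
  cls <- ifelse(pho_i & pho_j, "Pho-Pho",
                ifelse(!pho_i & !pho_j, "Phi-Phi", "Phi-Pho"))
  tally <- c(`Phi-Phi` = sum(cls == "Phi-Phi"),
             `Phi-Pho` = sum(cls == "Phi-Pho"),
             `Pho-Pho` = sum(cls == "Pho-Pho"))
  chains <- sort(unique(chain))
  ci <- pmin(chain[i], chain[j]); cj <- pmax(chain[i], chain[j])
  pair_key <- paste(ci, cj)
  partners <- unique(data.frame(a = ci, b = cj))
  per_chain <- data.frame(
    chain = chains,
    n_partners = vapply(chains, function(ch)
      sum(partners$a == ch | partners$b == ch), integer(1)),
    n_contacts = vapply(chains, function(ch)
      sum(ci == ch | cj == ch), integer(1)))
  structure(list(per_chain = per_chain, partner_pairs = partners,
                 class_tally = tally, n_contacts = length(i),
                 contacts = data.frame(i = i, j = j, class = cls,
                                       dist = sqrt(d2[hit])),
                 chains = chains),
            class = "contact_stats")
}

#' Chain clusters from the contact network
#'
#' Connected components of the chain-level partner graph; chains without
#' any partner are singleton clusters.
#'
#' @param x a \code{contact_stats} (or a \code{trajectory}, in which case
#'   [contact_stats()] is run first).
#' @param ... passed to [contact_stats()] when \code{x} is a trajectory.
#' @return integer vector of cluster sizes, sorted descending.
#' @export
cluster_proteins <- function(x, ...) {
  if (inherits(x, "trajectory")) x <- contact_stats(x, ...)
  stopifnot(inherits(x, "contact_stats"))
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(x$partner_pairs$a),
               to = as.character(x$partner_pairs$b)),
    directed = FALSE,
    vertices = data.frame(name = as.character(x$chains)))
  sort(igraph::components(g)$csize, decreasing = TRUE)
}
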