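#' Assemble a sparse-MRI reconstruction problem from a phantom
#'
#' Generates (or accepts) a Haar-sparse image, samples its k-space on a
#' random mask, and builds the wavelet-domain QUBO operators with ground
#' truth attached (the true Haar coefficients and their support), so that
#' [run_hybrid()] can track direction cosine and RMSE.
#'
#' @param image Optional square image matrix; when `NULL` a
#'   [generate_phantom()] is drawn.
#' @param side Image side (used when `image` is `NULL`).
#' @param compression k-space sampling rate.
#' @param sparseness Target Haar sparseness of the phantom.
#' @param gamma L2 smoothness weight.
#' @param seed Optional integer seed (mask and phantom).
#' @return An `mri_qubo` operator set with extra fields `image` (ground
#'   truth), `r_true` (its Haar coefficients, as a vector), `xi_true`
#'   (their 0/1 support) and `y` (sampled k-space data).
#' @export
mri_problem <- function(image = NULL, side = 64, compression = 0.4,
                        sparseness = 0.212, gamma = 1e-4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(image)) {
    image <- generate_phantom(side, target_sparseness = sparseness)
  }
  side <- nrow(image)
  mask <- make_sampling_mask(side, compression, include_dc = TRUE)
  y <- sample_kspace(image, mask)
  q <- build_mri_qubo(y, mask, side, gamma = gamma)
  w <- as.vector(haar_2d(image))
  # transform round-off leaves ~1e-16 residue in constructed zeros
  w[abs(w) <= 1e-10 * max(abs(w))] <- 0
  q$image <- image
  q$r_true <- w
  q$xi_true <- as.numeric(w != 0)
  q$y <- y
  q
}

#' Support-estimation benchmark across machine models and annealing
#'
#' Reproduces the support-recovery comparison: draws `n_samples` random
#' Gaussian instances, fixes the signal estimate to the true source
#' values, and lets each solver estimate the support of each shared
#' instance; reports one direction cosine (and final Hamiltonian at
#' \eqn{\lambda = \eta^2/2}) per (sample, solver).
#'
#' @param n_samples Number of random instances.
#' @param N Problem size.
#' @param alpha Compression ratio.
#' @param a Sparseness.
#' @param nu Observation-noise s.d.
#' @param eta Support threshold (constant).
#' @param solvers Subset of `"cac_wigner"`, `"positive_p"`,
#'   `"wigner_ol"`, `"sa"`.
#' @param seed Integer seed; instance `s` uses seed `seed + 7919 * s`,
#'   and all solvers share both the instance and the run seed, so reruns
#'   are reproducible bit-for-bit.
#' @param sa_schedule [anneal_schedule()] for the `"sa"` solver (default:
#'   exponential cooling 0.02 to 0.00002 over 46000 steps).
#' @param cfg_args Named list of [cim_config()] overrides applied on top
#'   of the per-model presets.
#' @return A tibble with columns `sample`, `solver`, `seed`,
#'   `direction_cosine`, `hamiltonian`, plus the instance parameters.
#' @export
support_bench <- function(n_samples = 50, N = 500, alpha = 0.6, a = 0.6,
                          nu = 0, eta = 0.05,
                          solvers = c("cac_wigner", "positive_p",
                                      "wigner_ol", "sa"),
                          seed = 1,
                          sa_schedule = anneal_schedule("exponential",
                                                        n_steps = 46000),
                          cfg_args = list()) {
  solvers <- match.arg(solvers, several.ok = TRUE)
  lam <- eta^2 / 2
  purrr::map_dfr(seq_len(n_samples), function(s) {
    inst_seed <- seed + 7919L * s
    prob <- generate_random_cs(N, alpha, a, nu, seed = inst_seed)
    R <- prob$x_true * prob$xi_true   # masked source signal, as it enters y
    purrr::map_dfr(solvers, function(sv) {
      run_seed <- inst_seed + 1L
      if (sv == "sa") {
        res <- sa_metropolis(prob, R, lam, sa_schedule, seed = run_seed)
        sigma <- res$sigma
      } else {
        cfg <- do.call(cim_preset,
                       c(list(model = sv, experiment = "artificial",
                              eta_init = eta, eta_end = eta), cfg_args))
        sigma <- run_cim(sv, prob, R, eta, cfg, seed = run_seed)$sigma
      }
      tibble::tibble(
        sample = s, solver = sv, seed = run_seed,
        direction_cosine = direction_cosine(prob$xi_true, sigma),
        hamiltonian = qubo_hamiltonian(R, sigma, prob, lambda = lam),
        N = N, alpha = alpha, a = a, nu = nu, eta = eta
      )
    })
  })
}

#' Alternating-minimisation benchmark over a parameter grid
#'
#' Runs the full hybrid solver over a grid of (sparseness, compression,
#' noise) cells, `n_samples` shared instances per cell, and reports the
#' final RMSE of every run together with per-cell means.
#'
#' @param a_grid,alpha_grid,nu_grid Numeric vectors defining the grid.
#' @param n_samples Instances per cell.
#' @param N Problem size.
#' @param solvers Machine models to compare.
#' @param n_iters Alternating iterations (default 51, matching the
#'   threshold-schedule denominator).
#' @param eta_end Final threshold (default 0.18).
#' @param tau Target amplitude; `NULL` picks 1 for noise-free cells,
#'   0.21 for `nu <= 0.075` and 0.15 beyond.
#' @param seed Integer seed (same derivation as [support_bench()]).
#' @return A tibble with one row per (cell, sample, solver) carrying
#'   `rmse`, `direction_cosine` and the full parameter provenance.
#' @export
cs_bench <- function(a_grid = c(0.2, 0.4), alpha_grid = 0.6, nu_grid = 0,
                     n_samples = 3, N = 200,
                     solvers = c("cac_wigner", "wigner_ol"),
                     n_iters = 51, eta_end = 0.18, tau = NULL, seed = 1) {
  solvers <- match.arg(solvers,
                       c("cac_wigner", "positive_p", "wigner_ol"),
                       several.ok = TRUE)
  grid <- expand.grid(a = a_grid, alpha = alpha_grid, nu = nu_grid,
                      sample = seq_len(n_samples))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    inst_seed <- seed + 7919L * i
    prob <- generate_random_cs(N, g$alpha, g$a, g$nu, seed = inst_seed)
    tau_i <- tau %||% if (g$nu == 0) 1 else if (g$nu <= 0.075) 0.21 else 0.15
    purrr::map_dfr(solvers, function(sv) {
      eta_init <- if (sv == "wigner_ol") 0.8 else 0.6
      cfg <- cim_preset(sv, "artificial", eta_init = eta_init,
                        eta_end = eta_end, tau = tau_i, velo = n_iters)
      fit <- run_hybrid(prob, sv, n_iters = n_iters, cfg = cfg,
                        cdp = "jacobi", seed = inst_seed + 1L)
      dplyr::mutate(glance(fit),
                    sample = g$sample, solver = sv, a = g$a,
                    alpha = g$alpha, nu = g$nu, N = N, tau = tau_i,
                    seed = inst_seed + 1L)
    })
  })
}

#' Sparse-MRI reconstruction demo across solvers and thresholds
#'
#' Builds a phantom reconstruction problem, computes a LASSO path over
#' `lasso_grid`, and runs the open-loop and CAC hybrid solvers over their
#' threshold grids (constant threshold per run, warm-started from the
#' LASSO solution), reporting the RMSE of every (solver, threshold) pair
#' and keeping the best reconstruction per solver.
#'
#' @param side Image side, a power of 2.
#' @param compression k-space sampling rate.
#' @param sparseness Target Haar sparseness of the phantom.
#' @param gamma L2 smoothness weight.
#' @param solvers Subset of `"lasso"`, `"wigner_ol"`, `"cac_wigner"`,
#'   `"positive_p"`.
#' @param eta_grid_cac,eta_grid_ol Final-threshold grids for the hybrid
#'   solvers. Each solver runs its best-performing schedule form: the
#'   open-loop model a constant threshold, the CAC models a threshold
#'   annealed from `4 * eta_end` down to `eta_end` over the first six
#'   iterations and held there (the CAC entry criterion acts on the
#'   softer scale `R_r h_r`, so a high initial threshold followed by
#'   constant-threshold refinement prunes the warm-start support much
#'   more reliably than a constant threshold).
#' @param lasso_grid L1-penalty grid.
#' @param n_iters_cac,n_iters_ol Alternating iterations (defaults 11
#'   and 31).
#' @param lasso_init_lam L1 penalty of the warm-start solution.
#' @param cg_tol,cg_max_iter Conjugate-gradient controls for the
#'   classical stage.
#' @param n_steps_cim Euler-Maruyama steps per CIM call.
#' @param seed Integer seed (phantom, mask and runs).
#' @param image Optional externally supplied image.
#' @return An object of class `mri_demo`: `results` (tibble with one row
#'   per solver/threshold: `solver`, `eta`, `rmse`, `seed`), `best`
#'   (named list of reconstructed images at each solver's best
#'   threshold), and `problem`.
#' @export
mri_demo <- function(side = 64, compression = 0.4, sparseness = 0.212,
                     gamma = 1e-4,
                     solvers = c("lasso", "wigner_ol", "cac_wigner"),
                     eta_grid_cac = c(0.0055, 0.008, 0.011, 0.016),
                     eta_grid_ol = c(0.0055, 0.011, 0.022),
                     lasso_grid = c(1e-4, 3e-4, 1e-3, 3e-3),
                     n_iters_cac = 11, n_iters_ol = 31,
                     lasso_init_lam = 3e-4,
                     cg_tol = 1e-8, cg_max_iter = 2000,
                     n_steps_cim = 1000, seed = 1, image = NULL) {
  solvers <- match.arg(solvers,
                       c("lasso", "wigner_ol", "cac_wigner", "positive_p"),
                       several.ok = TRUE)
  prob <- mri_problem(image, side, compression, sparseness, gamma,
                      seed = seed)
  side <- prob$side
  truth_img <- prob$image

  set.seed(seed + 1L)
  warm <- lasso_fista(prob, lam1 = lasso_init_lam, tol = 1e-8,
                      max_iter = 2000)$x

  rows <- list()
  best <- list()
  score <- function(R, sigma) recovery_rmse(R, sigma, prob$r_true, prob$xi_true)

  if ("lasso" %in% solvers) {
    res <- purrr::map_dfr(lasso_grid, function(lam1) {
      fit <- suppressWarnings(
        lasso_fista(prob, lam1 = lam1, tol = 1e-8, max_iter = 2000,
                    x_init = warm)
      )
      tibble::tibble(solver = "lasso", eta = lam1,
                     rmse = score(fit$x, as.numeric(fit$x != 0)),
                     support_size = sum(fit$x != 0))
    })
    rows <- c(rows, list(res))
    lam_best <- res$eta[which.min(res$rmse)]
    xb <- suppressWarnings(lasso_fista(prob, lam1 = lam_best, tol = 1e-8,
                                       max_iter = 2000, x_init = warm))$x
    best$lasso <- inverse_haar_2d(matrix(xb, side, side))
  }

  hybrid_one <- function(model, eta, n_iters) {
    cfg <- if (model == "wigner_ol") {
      cim_preset(model, "mri", eta_init = eta, eta_end = eta, n_steps = 50)
    } else {
      cim_preset(model, "mri", eta_init = 4 * eta, eta_end = eta,
                 velo = 6, n_steps = n_steps_cim)
    }
    suppressWarnings(
      run_hybrid(prob, model, n_iters = n_iters, cfg = cfg, R_init = warm,
                 cdp = "cgd", seed = seed + 2L,
                 tol = cg_tol, max_iter = cg_max_iter)
    )
  }
  for (model in intersect(solvers, c("wigner_ol", "cac_wigner", "positive_p"))) {
    grid_m <- if (model == "wigner_ol") eta_grid_ol else eta_grid_cac
    iters_m <- if (model == "wigner_ol") n_iters_ol else n_iters_cac
    fits <- purrr::map(grid_m, function(eta) hybrid_one(model, eta, iters_m))
    res <- purrr::map2_dfr(fits, grid_m, function(fit, eta) {
      tibble::tibble(solver = model, eta = eta,
                     rmse = score(fit$R, fit$sigma),
                     support_size = sum(fit$sigma))
    })
    rows <- c(rows, list(res))
    fb <- fits[[which.min(res$rmse)]]
    best[[model]] <- inverse_haar_2d(matrix(fb$R * fb$sigma, side, side))
  }

  results <- dplyr::mutate(dplyr::bind_rows(rows),
                           side = side, compression = compression,
                           sparseness = sparseness, gamma = gamma,
                           seed = seed)
  structure(list(results = results, best = best, problem = prob,
                 truth = truth_img),
            class = "mri_demo")
}

#' @export
print.mri_demo <- function(x, ...) {
  cat(sprintf("<mri_demo> side %d, %d solver/threshold runs\n",
              x$problem$side, nrow(x$results)))
  s <- dplyr::summarise(dplyr::group_by(x$results, .data$solver),
                        min_rmse = min(.data$rmse), .groups = "drop")
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' RMSE-vs-threshold plot of an MRI demo
#'
#' @param object An `mri_demo`.
#' @param ... Unused.
#' @return A ggplot object (log-scaled threshold axis).
#' @export
autoplot.mri_demo <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$eta, y = .data$rmse,
                               colour = .data$solver)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "threshold / L1 penalty", y = "RMSE",
                  title = "Sparse-MRI reconstruction error")
}

#' Histogram of support-benchmark direction cosines
#'
#' @param results Tibble from [support_bench()].
#' @return A ggplot object, one panel per solver.
#' @export
plot_support_bench <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$direction_cosine)) +
    ggplot2::geom_histogram(bins = 30, boundary = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$solver)) +
    ggplot2::labs(x = "final direction cosine", y = "count")
}
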