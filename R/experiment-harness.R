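#' Simulation scenario description
#'
#' The three study scenarios: a small number of smooth patch sources (drawn
#' from the MSP patch library without replacement, matching the MSP prior),
#' many point sources with no spatial extent (matching the minimum-norm
#' prior), or no sources at all (pure sensor noise).  Each active source is
#' given an independent white-noise time course; data are synthesised as a
#' single trial at the stated signal-to-noise ratio.  Setting
#' `permute_leadfields = TRUE` marks a negative control in which the model
#' lead fields have their channels randomly permuted before inversion,
#' destroying the geometric link between data and anatomy.
#'
#' @param kind `"patches"`, `"points"` or `"noise_only"`.
#' @param n_sources Number of active sources (defaults: 3 patches, 500
#'   points, 0 for noise).
#' @param methods Inversion methods to run (`"MSP"`, `"MNM"`).
#' @param n_samples Samples per trial (default 161).
#' @param sample_rate Sampling rate in Hz (default 200).
#' @param snr_db Signal-to-noise ratio in dB (default 0: average channel
#'   signal power equals the sensor noise level).
#' @param permute_leadfields Apply the permuted-channel control.
#' @param label Scenario label used in result tables.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("patches", "points", "noise_only"),
                          n_sources = NULL,
                          methods = c("MSP", "MNM"),
                          n_samples = 161, sample_rate = 200,
                          snr_db = 0, permute_leadfields = FALSE,
                          label = NULL) {
  kind <- match.arg(kind)
  if (is.null(n_sources)) {
    n_sources <- switch(kind, patches = 3L, points = 500L, noise_only = 0L)
  }
  if (kind == "noise_only") n_sources <- 0L
  stopifnot(n_sources >= 0)
  if (is.null(label)) {
    label <- switch(kind,
      patches = paste0("patches_", n_sources),
      points = paste0("points_", n_sources),
      noise_only = "noise_only")
    if (permute_leadfields) label <- paste0(label, "_permuted")
  }
  structure(
    list(kind = kind, n_sources = as.integer(n_sources),
         methods = match.arg(methods, several.ok = TRUE),
         n_samples = as.integer(n_samples), sample_rate = sample_rate,
         snr_db = snr_db, permute_leadfields = permute_leadfields,
         label = label),
    class = "scenario_spec"
  )
}

#' Simulate source currents for a scenario
#'
#' Patch scenarios draw distinct patch centres from the library (without
#' replacement) and give each patch's spatial profile an independent
#' unit-variance white-noise time course; point scenarios place delta
#' (single-vertex) sources at distinct random vertices; the noise-only
#' scenario returns zero currents.
#'
#' @param spec A [scenario_spec()].
#' @param mesh The source [cortical_mesh()].
#' @param library A [build_patch_library()] (required for patch scenarios).
#' @param seed Integer seed.
#' @return `N_d x n_samples` current matrix with attributes `support`
#'   (vertices with nonzero rows) and `centres` (source centre vertices).
#' @export
simulate_sources <- function(spec, mesh, library = NULL, seed = 1) {
  stopifnot(inherits(spec, "scenario_spec"))
  nd <- nrow(mesh$vertices)
  nt <- spec$n_samples
  J <- matrix(0, nd, nt)
  if (spec$kind == "noise_only" || spec$n_sources == 0L) {
    attr(J, "support") <- integer(0)
    attr(J, "centres") <- integer(0)
    return(J)
  }
  with_seed(seed, {
    if (spec$kind == "patches") {
      if (is.null(library)) stop("patch scenario needs a patch library", call. = FALSE)
      npat <- ncol(library$profiles)
      if (spec$n_sources > npat) {
        stop("more sources requested than patches available", call. = FALSE)
      }
      picks <- sample.int(npat, spec$n_sources)
      P <- as.matrix(library$profiles[, picks, drop = FALSE])
      tc <- matrix(stats::rnorm(spec$n_sources * nt), spec$n_sources, nt)
      J <- P %*% tc
      attr(J, "support") <- which(rowSums(abs(P)) > 0)
      attr(J, "centres") <- library$centres[picks]
      attr(J, "patches") <- picks
    } else {
      if (spec$n_sources > nd) {
        stop("more point sources requested than vertices", call. = FALSE)
      }
      verts <- sample.int(nd, spec$n_sources)
      J[verts, ] <- matrix(stats::rnorm(spec$n_sources * nt),
                           spec$n_sources, nt)
      attr(J, "support") <- sort(verts)
      attr(J, "centres") <- verts
    }
    J
  })
}

#' Synthesise single-trial sensor data at a target SNR
#'
#' `Y = s * K J + e` with i.i.d. Gaussian sensor noise of standard deviation
#' `noise_sd` and the signal scale `s` chosen so that the average signal
#' power over channels equals `noise_sd^2 * 10^(snr_db / 10)`.  The 0 dB
#' convention uses the nominal noise variance (not the realised sample
#' variance), so the power ratio is exact by construction.  Zero currents
#' (the noise-only scenario) bypass the scaling and return pure noise.
#'
#' @param J Source currents (`N_d x N_t`).
#' @param K Lead field (matrix or `leadfield`).
#' @param snr_db Target SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @param noise_sd Sensor noise standard deviation (default 1).
#' @return `N_c x N_t` data matrix; the applied signal scale is in attribute
#'   `signal_scale`.
#' @export
synthesize_sensor_data <- function(J, K, snr_db = 0, seed = 1, noise_sd = 1) {
  Km <- leadfield_matrix(K)
  J <- as.matrix(J)
  stopifnot(ncol(Km) == nrow(J))
  noise <- with_seed(seed, {
    matrix(stats::rnorm(nrow(Km) * ncol(J), sd = noise_sd), nrow(Km), ncol(J))
  })
  if (all(J == 0)) {
    out <- noise
    attr(out, "signal_scale") <- 0
    return(out)
  }
  sig <- Km %*% J
  mp <- mean(sig^2)  # average over channels (and samples) of signal power
  if (mp == 0) {
    stop("K J is identically zero: SNR is undefined for these sources",
         call. = FALSE)
  }
  s <- sqrt(noise_sd^2 * 10^(snr_db / 10) / mp)
  out <- s * sig + noise
  attr(out, "signal_scale") <- s
  out
}

#' Default experiment configuration
#'
#' Desk scale uses 642-vertex hemispheres (1284 sources in total; icosphere
#' granularity), 128 sensors, a 128-patch library, harmonic orders up to 20
#' and 8 repetitions.  Paper scale raises these to 2562-vertex hemispheres,
#' 274 sensors, 512 patches, order 42, 100 spatial modes and 16 repetitions.
#'
#' @param scale `"desk"` (default) or `"paper"`.
#' @param seed Master seed.
#' @return A config list accepted by [run_experiment()].
#' @export
default_config <- function(scale = c("desk", "paper"), seed = 1) {
  scale <- match.arg(scale)
  desk <- scale == "desk"
  list(
    seed = as.integer(seed),
    cortex = list(
      n_vertices = if (desk) 642 else 2562,
      base_radius = 50, amplitudes = 12 / (1:12), offset = 25
    ),
    sensors = list(
      n_channels = if (desk) 128 else 274,
      helmet_radius = 120, cap_fraction = 0.55
    ),
    Lmax = if (desk) 20 else 42,
    L_values = seq_len(if (desk) 20 else 42),
    sigma = 0,
    n_patches = if (desk) 128 else 512,
    fwhm = 10,
    n_spatial = if (desk) 60 else 100,
    n_temporal = 16,
    n_restarts = 1,
    threshold = 0.05,
    hyperpriors = "lognormal",
    n_repetitions = if (desk) 8 else 16,
    scenarios = list(
      scenario_spec("patches"),
      scenario_spec("points", n_sources = if (desk) 200 else 500),
      scenario_spec("noise_only", methods = "MSP"),
      scenario_spec("patches", methods = "MNM", permute_leadfields = TRUE)
    )
  )
}

# Documented per-cell seed scheme: every stochastic stage of a cell gets
# master + 100000 * scenario + 1000 * rep + offset, offsets 0..3 for
# source draw / sensor noise / channel permutation / inversion.
cell_seed <- function(master, scenario_idx, rep, offset) {
  as.integer((master + 100000L * scenario_idx + 1000L * rep + offset) %%
               .Machine$integer.max)
}

#' Run the full simulation experiment
#'
#' End-to-end reproduction of the simulation protocol at configurable
#' scale: generate a synthetic cortex, decompose it into its harmonic
#' surface family, compute lead fields for every member, simulate each
#' scenario's sources and sensor data at the stated SNR, invert every
#' repetition onto every surface under each method (all models projected
#' through one shared spatial projector so their evidences are
#' commensurable), pool log evidences over repetitions, and derive pairwise
#' posteriors, the HDH and its distortion bound per scenario and method.
#'
#' @param config A config list, see [default_config()].
#' @param progress Print per-scenario progress lines (default `FALSE`).
#'
#' @return An object of class `hdh_experiment`: `results` (tibble with one
#'   row per scenario x method x L x repetition), `comparison` (tibble with
#'   one row per scenario x method: HDH, indistinguishable flag, distortion
#'   bound in mm, MAP surviving model), `tables` (named list of
#'   [model_comparison_table()] objects), `distortion` (per-L distortion of
#'   the surface family), and `config`.
#' @export
run_experiment <- function(config = default_config(), progress = FALSE) {
  cfg <- config
  say <- function(...) if (progress) message(...)

  say("building anatomy and harmonic family")
  mesh <- generate_synthetic_cortex(
    n_vertices = cfg$cortex$n_vertices,
    base_radius = cfg$cortex$base_radius,
    amplitudes = cfg$cortex$amplitudes,
    offset = cfg$cortex$offset,
    seed = cfg$seed
  )
  fit <- fit_wfs(mesh, Lmax = cfg$Lmax, sigma = cfg$sigma)
  L_values <- sort(unique(c(cfg$L_values, cfg$Lmax)))
  fam <- harmonic_family(fit, L_values)
  sensors <- generate_sensor_array(
    n_channels = cfg$sensors$n_channels,
    helmet_radius = cfg$sensors$helmet_radius,
    cap_fraction = cfg$sensors$cap_fraction
  )

  say("computing lead fields for ", length(L_values), " surface models")
  lead <- lapply(fam$meshes[paste0("L", L_values)], function(mm) {
    compute_leadfield(mm, sensors)$K
  })
  K_ref <- lead[[paste0("L", cfg$Lmax)]]
  sv <- svd(K_ref)
  n_sp <- min(cfg$n_spatial, sum(sv$d > sv$d[1] * 1e-12))
  U <- t(sv$u[, seq_len(n_sp), drop = FALSE])
  library <- build_patch_library(fam$reference, cfg$n_patches, cfg$fwhm,
                                 seed = cfg$seed)

  rows <- list()
  tables <- list()
  comp_rows <- list()
  for (si in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[si]]
    say("scenario ", sc$label)
    for (rep in seq_len(cfg$n_repetitions)) {
      J <- simulate_sources(sc, fam$reference, library,
                            seed = cell_seed(cfg$seed, si, rep, 0L))
      Y <- synthesize_sensor_data(J, K_ref, sc$snr_db,
                                  seed = cell_seed(cfg$seed, si, rep, 1L))
      if (sc$permute_leadfields) {
        pseed <- cell_seed(cfg$seed, si, rep, 2L)
        lead_m <- lapply(lead, permute_leadfields, seed = pseed)
        Kp_ref <- lead_m[[paste0("L", cfg$Lmax)]]
        svp <- svd(Kp_ref)
        U_m <- t(svp$u[, seq_len(n_sp), drop = FALSE])
      } else {
        lead_m <- lead
        U_m <- U
      }
      Yu <- U_m %*% Y
      svy <- svd(Yu)
      n_tm <- min(cfg$n_temporal, sum(svy$d > svy$d[1] * 1e-12))
      V <- svy$v[, seq_len(n_tm), drop = FALSE]
      Yr <- Yu %*% V
      for (method in sc$methods) {
        for (L in L_values) {
          red <- structure(
            list(U = U_m, V = V, K = U_m %*% lead_m[[paste0("L", L)]],
                 Y = Yr, n_samples_full = ncol(Y)),
            class = "reduced_problem"
          )
          cell <- tryCatch({
            res <- invert(Y, lead_m[[paste0("L", L)]], method = method,
                          library = library, n_restarts = cfg$n_restarts,
                          seed = cell_seed(cfg$seed, si, rep, 3L),
                          hyperpriors = cfg$hyperpriors, reduced = red)
            tibble::tibble(
              scenario = sc$label, method = method, L = L, rep = rep,
              F = res$F, explained_variance = res$explained_variance,
              n_active = length(res$active), converged = res$converged,
              error = NA_character_
            )
          }, error = function(e) {
            tibble::tibble(
              scenario = sc$label, method = method, L = L, rep = rep,
              F = NA_real_, explained_variance = NA_real_,
              n_active = NA_integer_, converged = NA,
              error = conditionMessage(e)
            )
          })
          rows[[length(rows) + 1L]] <- cell
        }
      }
    }
  }
  results <- dplyr::bind_rows(rows)

  for (key in unique(paste(results$scenario, results$method, sep = "."))) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    ev <- dplyr::filter(results, .data$scenario == parts[1],
                        .data$method == parts[2], !is.na(.data$F))
    if (nrow(ev) == 0L) next
    tab <- model_comparison_table(ev[, c("L", "F", "rep")],
                                  threshold = cfg$threshold,
                                  reference_L = cfg$Lmax)
    tables[[key]] <- tab
    hdh <- attr(tab, "hdh")
    bound <- if (hdh > 0) {
      fam$distortion$distortion_mm[fam$distortion$L == hdh]
    } else NA_real_
    comp_rows[[key]] <- tibble::tibble(
      scenario = parts[1], method = parts[2],
      hdh = hdh,
      indistinguishable = attr(tab, "indistinguishable"),
      distortion_bound_mm = if (length(bound)) bound else NA_real_,
      map_L = glance(tab)$map_L
    )
  }

  structure(
    list(results = results,
         comparison = dplyr::bind_rows(comp_rows),
         tables = tables,
         distortion = fam$distortion,
         config = cfg),
    class = "hdh_experiment"
  )
}

#' @export
print.hdh_experiment <- function(x, ...) {
  cat("<hdh_experiment> ", nrow(x$results), " inversions, ",
      length(unique(x$results$scenario)), " scenario(s)\n", sep = "")
  print(x$comparison)
  invisible(x)
}

#' @rdname run_experiment
#' @param x An `hdh_experiment`.
#' @param ... Unused.
#' @export
tidy.hdh_experiment <- function(x, ...) x$results

#' @rdname run_experiment
#' @export
glance.hdh_experiment <- function(x, ...) x$comparison
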