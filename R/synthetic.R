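#' Simulate a native ESI spectrum of a quadruplex-forming RNA
#'
#' Generates a centroided peak list emulating a negative-mode native ESI
#' spectrum of a tetramolecular quadruplex system: monomer / dimer /
#' trimer / tetramer species in given proportions, each spread over a
#' charge-state distribution, the tetramer carrying its channel cations
#' (with optional extra adducts and, for ammonium, NH3-loss satellites),
#' isotope envelopes, Gaussian m/z jitter in ppm, and multiplicative
#' log-normal intensity noise. Defaults mirror the UAGGGU / potassium
#' system: species shares Q 62%, M 28%, D 10% (no trimers in ESI), the
#' quadruplex with three channel K+ over net charges 4- to 8-.
#'
#' @param strand An [rna_strand()] or sequence string (default "UAGGGU").
#' @param proportions Named shares of total signal for `M`, `D`, `T`, `Q`
#'   (normalised internally).
#' @param cation `"K"` or `"NH4"` for the tetramer channel cations.
#' @param x Channel cation count on the tetramer (3 for UAGGGU).
#' @param charge_weights Named list of per-species charge-state weight
#'   vectors (names = net charges). Defaults avoid strictly mass-degenerate
#'   pairs (a dimer at 4- coincides exactly in m/z with a monomer at 2-),
#'   which no m/z-based assignment could separate.
#' @param extra_adduct_frac Fraction of tetramer signal carrying one extra
#'   cation on a deprotonated phosphate (still a quadruplex).
#' @param nh3_split For ammonium only: weights over 0, 1, 2, ... NH3
#'   losses of the tetramer signal (satellites of source activation).
#' @param isotope_peaks Isotopologue bins simulated per ion (1 = bare
#'   monoisotopic centroid).
#' @param noise_cv Log-normal intensity coefficient of variation.
#' @param jitter_ppm Gaussian m/z jitter SD, ppm.
#' @param total_intensity Total ion current, arbitrary units.
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `peaks` (peak-list tibble), `truth` (generating
#'   proportions and parameters), and `candidates` (the exact species
#'   grid used for generation).
#' @export
simulate_esi_spectrum <- function(strand = "UAGGGU",
                                  proportions = c(M = 0.28, D = 0.10,
                                                  T = 0, Q = 0.62),
                                  cation = "K", x = 3L,
                                  charge_weights = list(
                                    M = c(`2` = 2, `3` = 1),
                                    D = c(`3` = 1),
                                    T = c(`3` = 1, `4` = 1),
                                    Q = c(`4` = 1, `5` = 3, `6` = 4,
                                          `7` = 2, `8` = 1)),
                                  extra_adduct_frac = 0.10,
                                  nh3_split = c(`0` = 0.7, `1` = 0.2, `2` = 0.1),
                                  isotope_peaks = 5L,
                                  noise_cv = 0.02, jitter_ppm = 2,
                                  total_intensity = 1e6, seed = 1L) {
  strand <- as_strand(strand)
  stopifnot(all(proportions >= 0), sum(proportions) > 0)
  proportions <- proportions / sum(proportions)
  orders <- c(M = 1L, D = 2L, T = 3L, Q = 4L)

  withr::with_seed(seed, {
    rows <- list()
    for (sp in names(proportions)) {
      if (proportions[[sp]] <= 0) next
      ord <- orders[[sp]]
      cw <- charge_weights[[sp]]
      cw <- cw / sum(cw)
      for (nm in names(cw)) {
        n <- as.integer(nm)
        base_int <- total_intensity * proportions[[sp]] * cw[[nm]]
        # adduct / satellite sub-species of the tetramer
        sub <- if (sp == "Q") {
          if (cation == "NH4") {
            s <- nh3_split / sum(nh3_split)
            tibble::tibble(x = x, nh3 = as.integer(names(s)),
                           frac = unname(s))
          } else {
            tibble::tibble(x = c(x, x + 1L), nh3 = 0L,
                           frac = c(1 - extra_adduct_frac, extra_adduct_frac))
          }
        } else {
          tibble::tibble(x = 0L, nh3 = 0L, frac = 1)
        }
        sub <- dplyr::filter(sub, .data$frac > 0, .data$nh3 <= .data$x)
        for (i in seq_len(nrow(sub))) {
          cat_i <- if (sub$x[i] > 0) cation else "none"
          rows[[length(rows) + 1L]] <- tibble::tibble(
            species = sp, order = ord, cation = cat_i, x = sub$x[i],
            h = n + sub$x[i], n = n, nh3 = sub$nh3[i],
            intensity = base_int * sub$frac[i],
            mz = mz_species(strand, order = ord, cation = cat_i,
                            x = sub$x[i], n = n, nh3_losses = sub$nh3[i])
          )
        }
      }
    }
    ions <- dplyr::bind_rows(rows)
    peaks <- purrr::pmap_dfr(ions, function(...) {
      ion <- tibble::tibble(...)
      if (isotope_peaks > 1L) {
        comp <- ion_composition(strand, dplyr::mutate(ion, class = "assembly"))
        pat <- isotope_pattern(comp, max_peaks = isotope_peaks)
        mzs <- ion$mz + (pat$mass - pat$mass[1]) / ion$n
        ints <- ion$intensity * pat$abundance
      } else {
        mzs <- ion$mz; ints <- ion$intensity
      }
      tibble::tibble(mz = mzs, intensity = ints)
    })
    peaks$mz <- peaks$mz * (1 + stats::rnorm(nrow(peaks), 0, jitter_ppm * 1e-6))
    if (noise_cv > 0) {
      sdlog <- sqrt(log(1 + noise_cv^2))
      peaks$intensity <- peaks$intensity *
        stats::rlnorm(nrow(peaks), -sdlog^2 / 2, sdlog)
    }
    peaks <- dplyr::arrange(peaks, .data$mz)
  })

  candidates <- dplyr::distinct(
    dplyr::mutate(ions, label = species_label(.data$order, .data$cation,
                                              .data$x, .data$n, .data$nh3),
                  class = "assembly"),
    .data$label, .data$class, .data$order, .data$cation, .data$x,
    .data$h, .data$n, .data$nh3, .data$mz
  )
  list(
    peaks = as_peak_list(peaks),
    truth = list(proportions = proportions, cation = cation, x = x,
                 noise_cv = noise_cv, jitter_ppm = jitter_ppm, seed = seed),
    candidates = candidates
  )
}

#' Simulate a CAD energy series of a quadruplex precursor
#'
#' Emulates collisionally activated dissociation of an isolated
#' quadruplex ion as phenomenological (logistic) species trajectories
#' versus laboratory-frame energy — the package models no kinetics, as
#' the analysis it feeds fits none. The surviving quadruplex follows
#' Q(E) = initial_q * 100 / (1 + exp((E - e_mid)/width)); the dissociated
#' share splits into trimer + monomer (the low-energy asymmetric channel;
#' for net charges >= 7 into dimer + monomer instead), a minor dimer
#' contribution capped at `dimer_max`, and covalent-cleavage products
#' ramping in above `frag_onset` to at most `frag_max`. Ammonium
#' precursors additionally spread surviving-Q signal over NH3-loss
#' satellites below the dissociation regime. Backbone c/y fragments are
#' biased toward overhang cleavage at low energy, decaying to the random
#' 40% at high energy. Each voltage point becomes a centroided peak list
#' (monoisotopic centroids) with log-normal intensity noise and ppm
#' jitter.
#'
#' @param strand,annot Strand and tetrad annotation.
#' @param cation,x,n Precursor description (default (Q+3K) at 5-).
#' @param voltages Collision-voltage grid, V.
#' @param e_mid,width Logistic midpoint and width of Q survival, eV.
#' @param initial_q Surviving-Q fraction at 0 eV (< 1 emulates unintended
#'   source/isolation activation of high-charge precursors).
#' @param frag_onset,frag_width,frag_max Covalent-product logistic onset
#'   (eV), width (eV), and asymptotic share (fraction).
#' @param dimer_max Maximum dimer share (fraction).
#' @param overhang_bias0,bias_decay Initial excess of overhang c/y share
#'   over the random 40% (0.4 gives the ~80% low-energy share) and its
#'   exponential decay constant in eV.
#' @param noise_cv,jitter_ppm Noise model, as in [simulate_esi_spectrum()].
#' @param total_intensity Total signal per energy point.
#' @param seed Integer seed.
#' @return A list with `series` (an [energy_series()]), `truth`
#'   (generating trajectories and parameters).
#' @export
simulate_cad_series <- function(strand = "UAGGGU",
                                annot = tetrad_annotation(6, 3:6, c("G", "G", "G", "U")),
                                cation = "K", x = 3L, n = 5L,
                                voltages = seq(2, 62, by = 4),
                                e_mid = 150, width = 15, initial_q = 1,
                                frag_onset = 180, frag_width = 30,
                                frag_max = 0.11, dimer_max = 0.02,
                                overhang_bias0 = 0.4, bias_decay = 80,
                                noise_cv = 0.02, jitter_ppm = 2,
                                total_intensity = 1e6, seed = 1L) {
  strand <- as_strand(strand)
  stopifnot(initial_q > 0, initial_q <= 1, width > 0)
  energies <- lab_frame_energy(voltages, n)

  logi <- function(E, mid, w) 1 / (1 + exp((E - mid) / w))
  q_frac <- initial_q * logi(energies, e_mid, width)
  f_frac <- frag_max * (1 - logi(energies, frag_onset, frag_width))
  rem <- pmax(0, 1 - q_frac - f_frac)
  d_frac <- pmin(dimer_max * (1 - logi(energies, e_mid + 2 * width, width)), rem / 3)
  rem2 <- rem - d_frac
  # asymmetric channel: equal T and M at onset, trimer decaying at high E;
  # high-charge precursors skip the trimer (T -> D + M is immediate)
  t_share <- if (n >= 7) 0.05 else 0.5 * exp(-pmax(0, energies - (e_mid + width)) / (4 * width))
  t_frac <- rem2 * t_share
  m_frac <- rem2 - t_frac
  # exact closure (the fragment logistic can overlap full Q survival), then
  # a detection floor: shares below 0.01% of the total are not observed
  tot_frac <- q_frac + t_frac + d_frac + m_frac + f_frac
  q_frac <- q_frac / tot_frac; t_frac <- t_frac / tot_frac
  d_frac <- d_frac / tot_frac; m_frac <- m_frac / tot_frac
  f_frac <- f_frac / tot_frac
  floor_at <- function(x) ifelse(x < 1e-4, 0, x)
  q_frac <- floor_at(q_frac); t_frac <- floor_at(t_frac)
  d_frac <- floor_at(d_frac); m_frac <- floor_at(m_frac)
  f_frac <- floor_at(f_frac)
  tot_frac <- q_frac + t_frac + d_frac + m_frac + f_frac
  q_frac <- q_frac / tot_frac; t_frac <- t_frac / tot_frac
  d_frac <- d_frac / tot_frac; m_frac <- m_frac / tot_frac
  f_frac <- f_frac / tot_frac

  truth_traj <- tibble::tibble(
    energy = energies, Q = 100 * q_frac, T = 100 * t_frac, D = 100 * d_frac,
    M = 100 * m_frac, F = 100 * f_frac
  )

  frag_ions <- enumerate_fragments(strand, annot, series = c("a", "c", "w", "y"))
  frag_ions <- dplyr::filter(frag_ions, .data$detectable)
  sites <- cleavage_sites(strand, annot)
  over_sites <- sites$site[sites$region == "overhang"]

  withr::with_seed(seed, {
    make_point <- function(E, qf, tf, df, mf, ff) {
      rows <- list()
      add <- function(mz, int) {
        rows[[length(rows) + 1L]] <<- tibble::tibble(mz = mz, intensity = int)
      }
      tot <- total_intensity
      # surviving quadruplex (with NH3-loss satellites for ammonium)
      if (qf > 0) {
        if (cation == "NH4") {
          p_loss <- 1 - logi(E, e_mid - 2.5 * width, width)  # satellites precede dissociation
          wts <- stats::dbinom(0:x, x, p_loss)
          for (k in 0:x) {
            if (wts[k + 1] < 1e-6) next
            add(mz_species(strand, 4L, cation, x, n, nh3_losses = k),
                tot * qf * wts[k + 1])
          }
        } else {
          add(mz_species(strand, 4L, cation, x, n), tot * qf)
        }
      }
      # noncovalent products: T keeps the cations, M leaves bare
      if (tf > 0) add(mz_species(strand, 3L, cation, x, n = 3L), tot * tf)
      if (mf > 0) add(mz_species(strand, 1L, "none", 0L, n = 2L), tot * mf)
      if (df > 0) add(mz_species(strand, 2L, "none", 0L, n = 3L), tot * df)
      # covalent products: half base loss, half backbone, shifting with E
      if (ff > 0) {
        base_share <- 0.7 * exp(-pmax(0, E - frag_onset) / (3 * frag_width)) + 0.1
        aw_share <- (1 - base_share) * pmin(0.4, 0.1 + E / 1500)
        cy_share <- 1 - base_share - aw_share
        gl <- neutral_loss_products(
          species_table(strand, 4L, cation, x = x, n = n), "guanine", 1L)
        add(gl$mz, tot * ff * base_share)
        over_share <- 0.4 + overhang_bias0 *
          exp(-pmax(0, E - min(energies)) / bias_decay)
        cy <- dplyr::filter(frag_ions, .data$series %in% c("c", "y"))
        cy_w <- ifelse(cy$site %in% over_sites,
                       over_share / sum(cy$site %in% over_sites),
                       (1 - over_share) / sum(!cy$site %in% over_sites))
        add((cy$mass - ms_constants[["proton"]]) / 1, tot * ff * cy_share * cy_w)
        aw <- dplyr::filter(frag_ions, .data$series %in% c("a", "w"))
        add((aw$mass - ms_constants[["proton"]]) / 1,
            tot * ff * aw_share / nrow(aw))
      }
      pk <- dplyr::bind_rows(rows)
      pk <- dplyr::filter(pk, .data$intensity > 0)
      pk$mz <- pk$mz * (1 + stats::rnorm(nrow(pk), 0, jitter_ppm * 1e-6))
      if (noise_cv > 0) {
        sdlog <- sqrt(log(1 + noise_cv^2))
        pk$intensity <- pk$intensity * stats::rlnorm(nrow(pk), -sdlog^2 / 2, sdlog)
      }
      as_peak_list(pk)
    }
    pls <- purrr::pmap(
      list(energies, q_frac, t_frac, d_frac, m_frac, f_frac), make_point)
  })

  series <- energy_series(voltages, pls,
                          precursor = list(cation = cation, x = x, n = n))
  list(series = series,
       truth = list(trajectories = truth_traj, e_mid = e_mid, width = width,
                    e50 = e_mid + width * log(max(initial_q * 100, 1e-9) / 50 - 1),
                    initial_q = initial_q, cation = cation, x = x, n = n,
                    seed = seed))
}

#' Simulate a UV melting trace
#'
#' Absorbance versus temperature generated from the melting model itself
#' (linear baseline plus one or two logistic sigmoids) with additive
#' Gaussian noise. A heating branch is always produced; optionally a
#' hysteretic cooling branch whose transitions are shifted to lower
#' temperature (slow tetramolecular re-association), which downstream
#' fitting must refuse to interpret.
#'
#' @param transitions Tibble or data frame with columns `amplitude` (AU,
#'   signed), `t_mid` (degrees C) and `width` (logistic w, degrees C; the
#'   10-90% span is 2 ln(9) w, so w ~ 3.4 gives the ~15 degree span of a
#'   stable quadruplex and w ~ 5.7 the ~25 degree span of a marginal one).
#' @param baseline Intercept and slope (AU, AU/degC).
#' @param t_range,by Temperature grid, degrees C.
#' @param noise_sd Additive Gaussian noise SD, AU.
#' @param wavelength Wavelength label, nm.
#' @param cooling Include a hysteretic cooling branch.
#' @param hysteresis_shift Downshift of cooling transitions, degrees C.
#' @param seed Integer seed.
#' @return A list with `curve` (tibble: `temperature`, `absorbance`,
#'   `wavelength`, `direction`) and `truth` (generating parameters).
#' @export
simulate_melting <- function(transitions = tibble::tibble(amplitude = 0.08,
                                                          t_mid = 60,
                                                          width = 3.4),
                             baseline = c(0.30, 5e-4),
                             t_range = c(15, 95), by = 0.5,
                             noise_sd = 0.002, wavelength = 260,
                             cooling = FALSE, hysteresis_shift = 10,
                             seed = 1L) {
  transitions <- tibble::as_tibble(transitions)
  stopifnot(all(c("amplitude", "t_mid", "width") %in% names(transitions)),
            all(transitions$width > 0), noise_sd >= 0)
  tt <- seq(t_range[1], t_range[2], by = by)
  model <- function(tv, shift = 0) {
    a <- baseline[1] + baseline[2] * tv
    for (i in seq_len(nrow(transitions))) {
      a <- a + transitions$amplitude[i] /
        (1 + exp(-(tv - (transitions$t_mid[i] - shift)) / transitions$width[i]))
    }
    a
  }
  withr::with_seed(seed, {
    heat <- tibble::tibble(
      temperature = tt,
      absorbance = model(tt) + stats::rnorm(length(tt), 0, noise_sd),
      wavelength = wavelength, direction = "heating"
    )
    curve <- heat
    if (cooling) {
      cool <- tibble::tibble(
        temperature = rev(tt),
        absorbance = model(rev(tt), shift = hysteresis_shift) +
          stats::rnorm(length(tt), 0, noise_sd),
        wavelength = wavelength, direction = "cooling"
      )
      curve <- dplyr::bind_rows(heat, cool)
    }
  })
  list(curve = curve,
       truth = list(transitions = transitions, baseline = baseline,
                    noise_sd = noise_sd, hysteresis_shift =
                      if (cooling) hysteresis_shift else 0, seed = seed))
}
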