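# 1:1 Langmuir interaction model for SPR sensorgrams: closed-form
# simulation and global nonlinear least-squares fitting, with the
# equilibrium dissociation constant reported as the exact ratio of the
# dissociation and association rates.

#' Equilibrium response of the 1:1 Langmuir isotherm
#'
#' @param Rmax surface capacity, RU.
#' @param KD equilibrium dissociation constant, M.
#' @param C analyte concentration, M.
#' @return R_eq = Rmax C / (C + KD), RU.
#' @export
equilibriumResponse <- function(Rmax, KD, C) {
  stopifnot(Rmax > 0, KD > 0, all(C >= 0))
  Rmax * C / (C + KD)
}

#' Closed-form 1:1 Langmuir response
#'
#' Association: R(t) = R_eq (1 - exp(-(ka C + kd) t)) with
#' R_eq = Rmax C / (C + kd/ka); dissociation: exponential decay from the
#' response at the end of association with rate kd.
#'
#' @param t time, seconds (vectorised).
#' @param C analyte concentration, M.
#' @param tAssocEnd end of the association phase, seconds.
#' @param ka association rate, 1/(M s).
#' @param kd dissociation rate, 1/s.
#' @param Rmax surface capacity, RU.
#' @return response in RU.
#' @export
langmuirResponse <- function(t, C, tAssocEnd, ka, kd, Rmax) {
  kobs <- ka * C + kd
  req <- Rmax * C / (C + kd / ka)
  r_end <- req * (1 - exp(-kobs * tAssocEnd))
  ifelse(t <= tAssocEnd,
         req * (1 - exp(-kobs * t)),
         r_end * exp(-kd * (t - tAssocEnd)))
}

#' Simulate a sensorgram
#'
#' Closed-form 1:1 Langmuir curve plus seeded Gaussian noise.
#'
#' @param ka,kd,Rmax kinetic truth (1/(M s), 1/s, RU); all positive.
#' @param conc analyte concentration, M (> 0).
#' @param times sample times, seconds (strictly increasing).
#' @param tAssocEnd end of association, seconds.
#' @param noiseSd Gaussian noise standard deviation, RU (default 0).
#' @param seed RNG seed (default 20240514).
#' @return a \linkS4class{Sensorgram}.
#' @export
simulateSensorgram <- function(ka, kd, Rmax, conc, times, tAssocEnd,
                               noiseSd = 0, seed = 20240514) {
  stopifnot(ka > 0, kd > 0, Rmax > 0, conc > 0, tAssocEnd > 0)
  resp <- langmuirResponse(times, conc, tAssocEnd, ka, kd, Rmax)
  if (noiseSd > 0) {
    old <- if (exists(".Random.seed", envir = .GlobalEnv))
      get(".Random.seed", envir = .GlobalEnv) else NULL
    set.seed(seed)
    resp <- resp + stats::rnorm(length(times), sd = noiseSd)
    if (!is.null(old)) assign(".Random.seed", old, envir = .GlobalEnv)
  }
  methods::new("Sensorgram", times = times, response = resp, conc = conc,
               tAssocEnd = tAssocEnd, noiseSd = noiseSd, seed = seed)
}

# crude data-driven starting values for the global fit
.langmuir_starts <- function(df) {
  Rmax0 <- max(df$response) * 1.2
  kd0 <- NA_real_
  diss <- df[df$t > df$tEnd & df$response > 0, , drop = FALSE]
  if (nrow(diss) > 4) {
    sl <- tryCatch(stats::coef(stats::lm(log(response) ~ I(t - tEnd),
                                         data = diss))[2],
                   error = function(e) NA_real_)
    if (is.finite(sl) && sl < 0) kd0 <- unname(-sl)
  }
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- 1 / max(df$tEnd)
  # equilibrium isotherm over per-curve association plateaus -> KD0
  plat <- vapply(split(df, df$curve), function(g) {
    a <- g[g$t <= g$tEnd, , drop = FALSE]
    stats::median(utils::tail(a$response, 5))
  }, numeric(1))
  concs <- vapply(split(df, df$curve), function(g) g$C[1], numeric(1))
  if (length(unique(concs)) < 2)
    return(list(ka = unname(kd0 / stats::median(concs)), kd = unname(kd0),
                Rmax = unname(Rmax0)))
  KD0 <- tryCatch({
    iso <- minpack.lm::nlsLM(plat ~ Rm * concs / (concs + K),
                             start = list(Rm = Rmax0, K = stats::median(concs)),
                             lower = c(1e-6, 1e-15),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    max(stats::coef(iso)["K"], 1e-15)
  }, error = function(e) stats::median(concs))
  list(ka = unname(kd0 / KD0), kd = unname(kd0), Rmax = unname(Rmax0))
}

#' Global 1:1 Langmuir fit
#'
#' Nonlinear least squares over (ka, kd, Rmax), fitted on log scale for
#' positivity, globally across all concentrations of an analyte series
#' (one shared Rmax: a single immobilised surface). KD is reported as
#' kd/ka exactly. Fitting a single concentration triggers an
#' identifiability warning (ka and Rmax are nearly confounded there).
#'
#' @param sensorgrams a \linkS4class{Sensorgram} or list of them.
#' @return a \linkS4class{KineticFit}.
#' @export
fitLangmuir <- function(sensorgrams) {
  if (methods::is(sensorgrams, "Sensorgram")) sensorgrams <- list(sensorgrams)
  stopifnot(length(sensorgrams) >= 1)
  df <- do.call(rbind, lapply(seq_along(sensorgrams), function(i) {
    sg <- sensorgrams[[i]]
    data.frame(t = sg@times, response = sg@response, C = sg@conc,
               tEnd = sg@tAssocEnd, curve = i)
  }))
  msgs <- character(0)
  if (length(unique(df$C)) < 2) {
    msgs <- c(msgs, "single analyte concentration: ka/Rmax weakly identifiable")
    warning(msgs[length(msgs)])
  }
  st <- .langmuir_starts(df)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ langmuirResponse(t, C, tEnd, exp(lka), exp(lkd), exp(lRm)),
      data = df,
      start = list(lka = log(st$ka), lkd = log(st$kd), lRm = log(st$Rmax)),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                           ptol = 1e-14)),
    error = function(e) stop("Langmuir fit did not converge: ",
                             conditionMessage(e)))
  co <- stats::coef(fit)
  ka <- exp(co[["lka"]]); kd <- exp(co[["lkd"]]); Rmax <- exp(co[["lRm"]])
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, 3))
  stderr <- c(ka = ka * se_log[["lka"]], kd = kd * se_log[["lkd"]],
              Rmax = Rmax * se_log[["lRm"]])
  methods::new("KineticFit", ka = ka, kd = kd, Rmax = Rmax, KD = kd / ka,
               rss = sum(stats::residuals(fit)^2), stderr = stderr,
               nobs = nrow(df), messages = msgs)
}

#' Write sensorgrams to CSV
#'
#' Columns: time_s, response_RU, conc_M, phase ("association"/"dissociation").
#'
#' @param sensorgrams a \linkS4class{Sensorgram} or list of them.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeSensorgrams <- function(sensorgrams, path) {
  if (methods::is(sensorgrams, "Sensorgram")) sensorgrams <- list(sensorgrams)
  df <- do.call(rbind, lapply(sensorgrams, function(sg) {
    data.frame(time_s = sg@times, response_RU = sg@response, conc_M = sg@conc,
               phase = ifelse(sg@times <= sg@tAssocEnd, "association",
                              "dissociation"))
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read sensorgrams from CSV
#'
#' Inverse of \code{\link{writeSensorgrams}}; one \linkS4class{Sensorgram}
#' per distinct concentration.
#'
#' @param path CSV path with columns time_s, response_RU, conc_M, phase.
#' @return list of \linkS4class{Sensorgram} objects.
#' @export
readSensorgrams <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_s", "response_RU", "conc_M", "phase")
  if (!all(need %in% names(df)))
    stop("sensorgram CSV needs columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$conc_M), function(g) {
    g <- g[order(g$time_s), , drop = FALSE]
    assoc <- g$time_s[g$phase == "association"]
    methods::new("Sensorgram", times = g$time_s, response = g$response_RU,
                 conc = g$conc_M[1],
                 tAssocEnd = if (length(assoc)) max(assoc) else max(g$time_s),
                 noiseSd = 0, seed = 0)
  })
}
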