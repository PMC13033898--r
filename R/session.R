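# Plain-text session container: a directory of JSON metadata and
# full-precision CSV arrays mirroring the hierarchical layout
# /meta, /raw, /gamma, /irf, /tpsf, /g1/<gate>, /xi, /rbfi, /truth.
# Numbers are written as %.17g so a write/read round trip is bit-identical,
# and every file stays diffable.

.SESSION_VERSION <- "1"

.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  out
}

.write_num_csv <- function(x, file) {
  x <- as.matrix(x)
  lines <- apply(x, 1, function(r) paste(.fmt_num(r), collapse = ","))
  writeLines(c(sprintf("# %d x %d", nrow(x), ncol(x)), lines), file)
}

.read_num_csv <- function(file) {
  lines <- readLines(file)
  body <- lines[-1]
  vals <- lapply(strsplit(body, ",", fixed = TRUE), as.numeric)
  do.call(rbind, vals)
}

.write_cx_csv <- function(x, stem) {
  .write_num_csv(Re(x), paste0(stem, "_re.csv"))
  .write_num_csv(Im(x), paste0(stem, "_im.csv"))
}

.read_cx_csv <- function(stem) {
  re <- .read_num_csv(paste0(stem, "_re.csv"))
  im <- .read_num_csv(paste0(stem, "_im.csv"))
  matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
}

.write_json <- function(x, file) {
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
}

#' Assemble a processing session
#'
#' A session bundles the stages of one acquisition or simulation run:
#' configuration and seed metadata plus any of the optional data groups. All
#' groups except `meta` are optional, so partially processed sessions load
#' fine.
#'
#' @param config the run configuration (a list).
#' @param seed the root seed; required whenever stochastic content (`gamma`,
#'   `raw`) is included.
#' @param irf,tpsf,gamma,g1,xi,rbfi,truth,raw optional components: an
#'   `irf_record`, a `tpsf_record`, a `gamma_series`, a named list of
#'   `g1_record`s, decay-rate and rBFi tables
#'   (`list(values, times, gates)`), simulator ground truth, and raw
#'   `sweep_frames`.
#' @return An object of class `tof_session`.
#' @export
tof_session <- function(config = list(), seed = NULL, irf = NULL,
                        tpsf = NULL, gamma = NULL, g1 = NULL, xi = NULL,
                        rbfi = NULL, truth = NULL, raw = NULL) {
  s <- structure(
    list(
      meta = list(version = .SESSION_VERSION, seed = seed, config = config),
      irf = irf, tpsf = tpsf, gamma = gamma, g1 = g1, xi = xi, rbfi = rbfi,
      truth = truth, raw = raw
    ),
    class = "tof_session"
  )
  .validate_session(s)
  s
}

.validate_session <- function(s) {
  stochastic <- !is.null(s$gamma) || !is.null(s$raw)
  if (stochastic && is.null(s$meta$seed)) {
    stop("stochastic content requires meta$seed")
  }
  invisible(s)
}

#' Write a session to a plain-text directory container
#'
#' @param session a [tof_session()].
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path) {
  stopifnot(inherits(session, "tof_session"))
  .validate_session(session)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  .write_json(session$meta, file.path(path, "meta.json"))
  if (!is.null(session$irf)) {
    d <- file.path(path, "irf")
    dir.create(d, showWarnings = FALSE)
    .write_num_csv(cbind(session$irf$tof_axis, session$irf$curve),
                   file.path(d, "curve.csv"))
    .write_json(list(peak_tof = session$irf$peak_tof,
                     fwhm = session$irf$fwhm, units = "s"),
                file.path(d, "meta.json"))
  }
  if (!is.null(session$tpsf)) {
    d <- file.path(path, "tpsf")
    dir.create(d, showWarnings = FALSE)
    mag <- session$tpsf$magnitude
    for (ch in seq_len(dim(mag)[3])) {
      .write_num_csv(mag[, , ch, drop = FALSE][, , 1],
                     file.path(d, sprintf("ch%02d.csv", ch)))
    }
    .write_num_csv(session$tpsf$tof_axis, file.path(d, "tof_axis.csv"))
    .write_json(list(n_sweeps = session$tpsf$n_sweeps,
                     acquisition_time = session$tpsf$acquisition_time,
                     n_channels = dim(mag)[3], units = "s"),
                file.path(d, "meta.json"))
  }
  if (!is.null(session$gamma)) {
    d <- file.path(path, "gamma")
    dir.create(d, showWarnings = FALSE)
    v <- session$gamma$values
    for (ch in seq_len(dim(v)[3])) {
      x <- v[, , ch, drop = FALSE]
      dim(x) <- dim(v)[1:2]
      .write_cx_csv(x, file.path(d, sprintf("ch%02d", ch)))
    }
    .write_num_csv(session$gamma$tof_axis, file.path(d, "tof_axis.csv"))
    tm <- session$gamma$timing
    .write_json(list(n_channels = dim(v)[3], sweep_rate = tm$sweep_rate,
                     sweep_bandwidth = tm$sweep_bandwidth,
                     adc_rate = tm$adc_rate,
                     samples_per_sweep = tm$samples_per_sweep,
                     amplitude = session$gamma$amplitude,
                     seed = session$gamma$seed, units = "s"),
                file.path(d, "meta.json"))
  }
  if (!is.null(session$g1)) {
    for (i in seq_along(session$g1)) {
      rec <- session$g1[[i]]
      d <- file.path(path, "g1", sprintf("gate%02d", i))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      for (ch in seq_len(dim(rec$values)[3])) {
        x <- rec$values[, , ch, drop = FALSE]
        dim(x) <- dim(rec$values)[1:2]
        .write_cx_csv(x, file.path(d, sprintf("ch%02d", ch)))
      }
      .write_num_csv(rec$lag_axis, file.path(d, "lag_axis.csv"))
      .write_num_csv(rec$times, file.path(d, "times.csv"))
      .write_json(list(tof_gate = rec$tof_gate,
                       output_rate = rec$output_rate, block = rec$block,
                       stride = rec$stride,
                       n_channels = dim(rec$values)[3],
                       zero_lag_excluded = rec$zero_lag_excluded,
                       denoised = isTRUE(rec$denoised), units = "s"),
                  file.path(d, "meta.json"))
    }
  }
  for (tab in c("xi", "rbfi")) {
    if (is.null(session[[tab]])) next
    d <- file.path(path, tab)
    dir.create(d, showWarnings = FALSE)
    .write_num_csv(session[[tab]]$values, file.path(d, "values.csv"))
    .write_num_csv(session[[tab]]$times, file.path(d, "times.csv"))
    .write_num_csv(session[[tab]]$gates, file.path(d, "gates.csv"))
  }
  if (!is.null(session$truth)) {
    .write_json(session$truth, file.path(path, "truth.json"))
  }
  if (!is.null(session$raw)) {
    d <- file.path(path, "raw")
    dir.create(d, showWarnings = FALSE)
    v <- session$raw$samples
    for (ch in seq_len(dim(v)[3])) {
      x <- v[, , ch, drop = FALSE]
      dim(x) <- dim(v)[1:2]
      .write_num_csv(x, file.path(d, sprintf("ch%02d.csv", ch)))
    }
    .write_json(list(n_channels = dim(v)[3], bins = session$raw$bins,
                     tof_axis = session$raw$tof_axis),
                file.path(d, "meta.json"))
  }
  invisible(path)
}

#' Read a session container back from disk
#'
#' @param path directory written by [write_session()].
#' @return A `tof_session`.
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(as.character(meta$version), .SESSION_VERSION)) {
    stop("session container version mismatch: migration required")
  }
  s <- structure(
    list(meta = meta, irf = NULL, tpsf = NULL, gamma = NULL, g1 = NULL,
         xi = NULL, rbfi = NULL, truth = NULL, raw = NULL),
    class = "tof_session"
  )
  rd <- function(...) file.path(path, ...)
  if (dir.exists(rd("irf"))) {
    m <- .read_num_csv(rd("irf", "curve.csv"))
    im <- jsonlite::read_json(rd("irf", "meta.json"), simplifyVector = TRUE)
    s$irf <- structure(
      list(curve = m[, 2], tof_axis = m[, 1], peak_tof = im$peak_tof,
           fwhm = im$fwhm),
      class = "irf_record"
    )
  }
  if (dir.exists(rd("tpsf"))) {
    im <- jsonlite::read_json(rd("tpsf", "meta.json"), simplifyVector = TRUE)
    chs <- lapply(seq_len(im$n_channels), function(ch) {
      .read_num_csv(rd("tpsf", sprintf("ch%02d.csv", ch)))
    })
    mag <- array(0, dim = c(nrow(chs[[1]]), ncol(chs[[1]]), length(chs)))
    for (ch in seq_along(chs)) mag[, , ch] <- chs[[ch]]
    s$tpsf <- structure(
      list(magnitude = mag,
           tof_axis = as.numeric(.read_num_csv(rd("tpsf", "tof_axis.csv"))),
           n_sweeps = im$n_sweeps, acquisition_time = im$acquisition_time),
      class = "tpsf_record"
    )
  }
  if (dir.exists(rd("gamma"))) {
    im <- jsonlite::read_json(rd("gamma", "meta.json"),
                              simplifyVector = TRUE)
    chs <- lapply(seq_len(im$n_channels), function(ch) {
      .read_cx_csv(rd("gamma", sprintf("ch%02d", ch)))
    })
    v <- array(complex(real = 0, imaginary = 0),
               dim = c(nrow(chs[[1]]), ncol(chs[[1]]), length(chs)))
    for (ch in seq_along(chs)) v[, , ch] <- chs[[ch]]
    timing <- sweep_timing(sweep_rate = im$sweep_rate,
                           sweep_bandwidth = im$sweep_bandwidth,
                           adc_rate = im$adc_rate,
                           samples_per_sweep = im$samples_per_sweep)
    s$gamma <- structure(
      list(values = v,
           tof_axis = as.numeric(.read_num_csv(rd("gamma", "tof_axis.csv"))),
           timing = timing, amplitude = im$amplitude, seed = im$seed,
           truth = NULL),
      class = "gamma_series"
    )
  }
  if (dir.exists(rd("g1"))) {
    gates <- sort(list.dirs(rd("g1"), recursive = FALSE))
    s$g1 <- lapply(gates, function(d) {
      im <- jsonlite::read_json(file.path(d, "meta.json"),
                                simplifyVector = TRUE)
      chs <- lapply(seq_len(im$n_channels), function(ch) {
        .read_cx_csv(file.path(d, sprintf("ch%02d", ch)))
      })
      v <- array(complex(real = 0, imaginary = 0),
                 dim = c(nrow(chs[[1]]), ncol(chs[[1]]), length(chs)))
      for (ch in seq_along(chs)) v[, , ch] <- chs[[ch]]
      structure(
        list(values = v,
             lag_axis = as.numeric(.read_num_csv(file.path(d,
                                                           "lag_axis.csv"))),
             tof_gate = im$tof_gate,
             times = as.numeric(.read_num_csv(file.path(d, "times.csv"))),
             output_rate = im$output_rate, block = im$block,
             stride = im$stride, zero_lag_excluded = im$zero_lag_excluded,
             denoised = im$denoised),
        class = "g1_record"
      )
    })
    names(s$g1) <- basename(gates)
  }
  for (tab in c("xi", "rbfi")) {
    if (!dir.exists(rd(tab))) next
    s[[tab]] <- list(
      values = .read_num_csv(rd(tab, "values.csv")),
      times = as.numeric(.read_num_csv(rd(tab, "times.csv"))),
      gates = as.numeric(.read_num_csv(rd(tab, "gates.csv")))
    )
  }
  if (file.exists(rd("truth.json"))) {
    s$truth <- jsonlite::read_json(rd("truth.json"), simplifyVector = TRUE)
  }
  if (dir.exists(rd("raw"))) {
    im <- jsonlite::read_json(rd("raw", "meta.json"), simplifyVector = TRUE)
    chs <- lapply(seq_len(im$n_channels), function(ch) {
      .read_num_csv(rd("raw", sprintf("ch%02d.csv", ch)))
    })
    v <- array(0, dim = c(nrow(chs[[1]]), ncol(chs[[1]]), length(chs)))
    for (ch in seq_along(chs)) v[, , ch] <- chs[[ch]]
    s$raw <- structure(
      list(samples = v, bins = im$bins, tof_axis = im$tof_axis),
      class = "sweep_frames"
    )
  }
  .validate_session(s)
  s
}
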