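## Plain-text I/O. No community standard exists for ENDOR/ELDOR-NMR
## spectra, so everything is diff-able structured text:
##  - spectra: two numeric columns (axis, amplitude), whitespace or comma
##    delimited, '#'-comment header carrying kind and axis units;
##  - tensor sets: one whitespace-delimited record per nucleus with a header
##    row (id isotope a_iso t_xx t_yy t_zz alpha_deg beta_deg gamma_deg and
##    optional p_xx p_yy p_zz q_alpha_deg q_beta_deg q_gamma_deg);
##  - spin systems: key = value lines (nu_obs_GHz, g, temperature_K, D_GHz,
##    E_GHz, optional nuclei = <tensor-set path>).
## Angles are degrees at the file boundary, radians internally.

#' Read a two-column spectrum file
#'
#' @param path File path.
#' @param kind Spectrum kind; default taken from a `# kind:` header line if
#'   present, else `"fieldsweep"`.
#' @return [spectrum_1d()]; the axis is sorted ascending, duplicate axis
#'   values are rejected.
#' @export
read_spectrum <- function(path, kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  if (is.null(kind)) {
    km <- regmatches(hdr, regexpr("(?<=kind:)\\s*\\S+", hdr, perl = TRUE))
    kind <- if (length(km)) trimws(km[1]) else "fieldsweep"
  }
  body_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(body_idx) < 2L) stop("spectrum file has fewer than 2 data rows",
                                  call. = FALSE)
  parse_row <- function(i) {
    parts <- strsplit(trimws(lines[i]), "[,[:space:]]+")[[1]]
    vals <- suppressWarnings(as.numeric(parts))
    if (length(vals) < 2L || anyNA(vals[1:2])) {
      stop("non-numeric spectrum row at line ", i, ": '", lines[i], "'",
           call. = FALSE)
    }
    vals[1:2]
  }
  m <- t(vapply(body_idx, parse_row, numeric(2)))
  ord <- order(m[, 1])
  ax <- m[ord, 1]
  if (any(diff(ax) == 0)) {
    dup <- body_idx[ord][which(diff(ax) == 0) + 1L]
    stop("duplicate axis value at line ", dup[1], call. = FALSE)
  }
  spectrum_1d(ax, m[ord, 2], kind = kind, meta = list(path = path))
}

#' Write a spectrum file
#'
#' @param spec [spectrum_1d()].
#' @param path Output path.
#' @param digits Significant digits (default 15, round-trip lossless).
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spec, path, digits = 15) {
  stopifnot(inherits(spec, "spectrum_1d"))
  unit <- if (spec$kind == "fieldsweep") "mT" else "MHz offset"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# kind: %s", spec$kind),
               sprintf("# axis: %s", unit)), con)
  writeLines(sprintf("%.*g %.*g", digits, spec$axis, digits,
                     spec$amplitude), con)
  invisible(path)
}

.TENSOR_COLS <- c("id", "isotope", "a_iso", "t_xx", "t_yy", "t_zz",
                  "alpha_deg", "beta_deg", "gamma_deg")
.QUAD_COLS <- c("p_xx", "p_yy", "p_zz", "q_alpha_deg", "q_beta_deg",
                "q_gamma_deg")

#' Read a tensor-set file
#'
#' One whitespace-delimited record per nucleus; couplings in MHz, Euler
#' angles in degrees (ZYZ intrinsic, principal axes to molecular frame).
#' Dipolar traces up to 1e-3 MHz are re-tracelessed with a warning; larger
#' ones are errors. Quadrupole columns may be `NA` for nuclei without one.
#'
#' @param path File path.
#' @param source Source tag for the returned set; default from a
#'   `# source:` header line, else `"file"`.
#' @return [tensor_set()].
#' @export
read_tensor_set <- function(path, source = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (is.null(source)) {
    hdr <- grep("^\\s*#", lines, value = TRUE)
    sm <- regmatches(hdr, regexpr("(?<=source:)\\s*\\S+", hdr, perl = TRUE))
    source <- if (length(sm)) trimws(sm[1]) else "file"
  }
  df <- utils::read.table(text = lines, header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  miss <- setdiff(.TENSOR_COLS, names(df))
  if (length(miss)) stop("tensor-set file missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate nucleus identities in ", path,
                                 call. = FALSE)
  deg <- pi / 180
  tensors <- lapply(seq_len(nrow(df)), function(i) {
    tr <- df$t_xx[i] + df$t_yy[i] + df$t_zz[i]
    tpv <- c(df$t_xx[i], df$t_yy[i], df$t_zz[i])
    if (abs(tr) > 1e-3) {
      stop("dipolar tensor of '", df$id[i], "' has trace ", signif(tr, 3),
           " MHz (tolerance 1e-3)", call. = FALSE)
    }
    if (abs(tr) > 1e-6) {
      warning("re-tracelessing dipolar tensor of '", df$id[i], "' (trace ",
              signif(tr, 3), " MHz)", call. = FALSE)
      tpv <- tpv - tr / 3
    }
    quad <- NULL
    if (all(.QUAD_COLS %in% names(df)) && !is.na(df$p_xx[i])) {
      ppv <- c(df$p_xx[i], df$p_yy[i], df$p_zz[i])
      ppv <- ppv - sum(ppv) / 3
      quad <- quadrupole_tensor(ppv, euler_angles(df$q_alpha_deg[i] * deg,
                                                  df$q_beta_deg[i] * deg,
                                                  df$q_gamma_deg[i] * deg))
    }
    hyperfine_tensor(df$isotope[i], df$a_iso[i], tpv,
                     frame = euler_angles(df$alpha_deg[i] * deg,
                                          df$beta_deg[i] * deg,
                                          df$gamma_deg[i] * deg),
                     id = df$id[i], quad = quad)
  })
  tensor_set(tensors, source = source)
}

#' Write a tensor-set file
#'
#' @param tensors [tensor_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tensor_set <- function(tensors, path) {
  stopifnot(inherits(tensors, "tensor_set"))
  rad2deg <- 180 / pi
  rows <- lapply(tensors$tensors, function(h) {
    base <- data.frame(id = h$id, isotope = h$nucleus,
                       a_iso = h$a_iso_mhz,
                       t_xx = h$t_principal[1], t_yy = h$t_principal[2],
                       t_zz = h$t_principal[3],
                       alpha_deg = h$frame$alpha * rad2deg,
                       beta_deg = h$frame$beta * rad2deg,
                       gamma_deg = h$frame$gamma * rad2deg,
                       stringsAsFactors = FALSE)
    if (!is.null(h$quad)) {
      base[, .QUAD_COLS] <- c(h$quad$p_principal,
                              h$quad$frame$alpha * rad2deg,
                              h$quad$frame$beta * rad2deg,
                              h$quad$frame$gamma * rad2deg)
    } else {
      base[, .QUAD_COLS] <- NA_real_
    }
    base
  })
  df <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# source: %s", tensors$source), con)
  utils::write.table(format(df, digits = 12, trim = TRUE), con,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

.SPIN_KEYS <- c("nu_obs_GHz", "g", "temperature_K", "D_GHz", "E_GHz",
                "nuclei")

#' Read a spin-system parameter file
#'
#' Key = value text with fields `nu_obs_GHz`, `g`, `temperature_K`,
#' `D_GHz`, `E_GHz` and optionally `nuclei` (path to a tensor-set file,
#' relative to the parameter file). Unknown keys trigger a warning and are
#' ignored.
#'
#' @param path File path.
#' @return List with `settings` ([spectrometer_settings()]), `zfs`
#'   ([zfs_parameters()]) and `tensors` ([tensor_set()] or `NULL`).
#' @export
read_spin_system <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed key = value line: '", lines[bad][1], "'",
                     call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  unknown <- setdiff(keys, .SPIN_KEYS)
  if (length(unknown)) {
    warning("ignoring unknown keys: ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  getnum <- function(key, default = NULL) {
    i <- match(key, keys)
    if (is.na(i)) {
      if (is.null(default)) stop("missing required key '", key, "'",
                                 call. = FALSE)
      return(default)
    }
    v <- suppressWarnings(as.numeric(vals[i]))
    if (is.na(v)) stop("non-numeric value for '", key, "'", call. = FALSE)
    v
  }
  settings <- spectrometer_settings(getnum("nu_obs_GHz", 94),
                                    getnum("g", 2.0023),
                                    getnum("temperature_K", 6))
  zfs <- zfs_parameters(getnum("D_GHz"), getnum("E_GHz", 0))
  tensors <- NULL
  i <- match("nuclei", keys)
  if (!is.na(i)) {
    tpath <- vals[i]
    if (!file.exists(tpath)) tpath <- file.path(dirname(path), vals[i])
    tensors <- read_tensor_set(tpath)
  }
  list(settings = settings, zfs = zfs, tensors = tensors)
}

#' Write a spin-system parameter file
#'
#' @param settings [spectrometer_settings()].
#' @param zfs [zfs_parameters()].
#' @param path Output path.
#' @param nuclei_path Optional tensor-set path to reference.
#' @return `path`, invisibly.
#' @export
write_spin_system <- function(settings, zfs, path, nuclei_path = NULL) {
  out <- c(sprintf("nu_obs_GHz = %.10g", settings$nu_obs_ghz),
           sprintf("g = %.10g", settings$g),
           sprintf("temperature_K = %.10g", settings$temperature_k),
           sprintf("D_GHz = %.10g", zfs$d_ghz),
           sprintf("E_GHz = %.10g", zfs$e_ghz))
  if (!is.null(nuclei_path)) out <- c(out, paste("nuclei =", nuclei_path))
  writeLines(out, path)
  invisible(path)
}
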