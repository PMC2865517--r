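# Delimited-text trace format, flat config files and run manifests.

#' Write a voltage trace to delimited text
#'
#' Tab-separated table with a header line (\code{time_ms}, \code{v_mV},
#' optional hidden-truth columns); metadata (noise SD, seed, model dt) is
#' stored in '#' comment lines so a written trace reads back identically.
#'
#' @param trace a trace data frame as returned by [make_observations()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- attributes(trace)[c("noise_sd", "seed", "dt")]
  for (nm in names(meta))
    if (!is.null(meta[[nm]]))
      writeLines(sprintf("# %s: %.17g", nm, meta[[nm]]), con)
  writeLines(paste(names(trace), collapse = "\t"), con)
  write.table(format(trace, digits = 17, trim = TRUE, scientific = TRUE),
              con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a voltage trace written by [write_trace()]
#'
#' @param path input file.
#' @return Trace data frame (columns time_ms, v_mV, any truth columns)
#'   with noise_sd / seed / dt attributes restored.
#' @export
read_trace <- function(path) {
  lines <- readLines(path)
  is_comment <- grepl("^#", lines)
  meta <- list()
  for (ln in lines[is_comment]) {
    m <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[trimws(m[2])]] <- as.numeric(m[3])
  }
  body <- lines[!is_comment]
  if (!length(body)) stop("no data in ", path)
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (!all(c("time_ms", "v_mV") %in% header))
    stop("malformed header in ", path, ": need columns time_ms and v_mV")
  df <- read.table(text = body[-1], sep = "\t", col.names = header)
  if (any(!is.finite(df$time_ms)) || any(!is.finite(df$v_mV))) {
    bad <- which(!is.finite(df$time_ms) | !is.finite(df$v_mV))[1]
    stop("non-finite values at data line ", bad, " of ", path)
  }
  if (any(diff(df$time_ms) <= 0)) {
    bad <- which(diff(df$time_ms) <= 0)[1]
    stop("non-monotone time at data line ", bad + 1, " of ", path)
  }
  for (nm in names(meta)) attr(df, nm) <- meta[[nm]]
  df
}

# schema of the flat configuration namespace: default value + unit
config_schema <- function() {
  list(
    C_m = list(1, "uF/cm^2"), g_Na = list(100, "mS/cm^2"),
    g_K = list(40, "mS/cm^2"), g_AHP = list(0.01, "mS/cm^2"),
    g_KL = list(0.05, "mS/cm^2"), g_NaL = list(0.0175, "mS/cm^2"),
    g_ClL = list(0.05, "mS/cm^2"), phi = list(3, "1"),
    g_Ca = list(0.1, "mS/cm^2"), E_Ca = list(120, "mV"),
    Cl_i = list(6, "mM"), Cl_o = list(130, "mM"),
    rho = list(1.25, "mM/s"), G_glia = list(66, "mM/s"),
    eps = list(1.2, "1/s"), K_bath = list(3, "mM"),
    beta_vol = list(7, "1"), gamma = list(0.0445, "mM*cm^2/ucoul"),
    delta = list(0.278, "1/s"), therm_mV = list(26.64, "mV"),
    g_inh = list(0.84, "mS/cm^2"), g_exc = list(0.17, "mS/cm^2"),
    tau_e = list(4, "ms"), tau_i = list(8, "ms"),
    E_exc = list(0, "mV"), E_inh = list(-80, "mV"),
    s_theta = list(-20, "mV"), s_slope = list(3, "mV"),
    eta_theta = list(-40, "mV"), eta_slope = list(3, "mV"),
    tau_eta = list(1000, "ms"), eta_c = list(0.5, "1"),
    sigma_chi = list(0.05, "1")
  )
}

#' Load a flat model configuration
#'
#' YAML file with one key per model symbol (\code{g_Na: 100} or
#' \code{g_Na: {value: 100, unit: mS/cm^2}}).  Unknown keys are rejected;
#' missing keys are filled with the shipped defaults; a stated unit must
#' match the schema.  An empty or absent file yields the full default set.
#'
#' @param path YAML file, or NULL for pure defaults.
#' @return Named list of parameter values covering the full schema.
#' @export
load_config <- function(path = NULL) {
  schema <- config_schema()
  vals <- lapply(schema, `[[`, 1)
  if (!is.null(path) && file.exists(path)) {
    user <- yaml::read_yaml(path)
    if (length(user)) {
      unknown <- setdiff(names(user), names(schema))
      if (length(unknown))
        stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
      for (nm in names(user)) {
        u <- user[[nm]]
        if (is.list(u)) {
          if (!is.null(u$unit) && u$unit != schema[[nm]][[2]])
            stop("unit mismatch for ", nm, ": expected ", schema[[nm]][[2]],
                 ", got ", u$unit)
          u <- u$value
        }
        if (!is.numeric(u) || !is.finite(u))
          stop("non-numeric value for ", nm)
        vals[[nm]] <- u
      }
    }
  }
  cond <- grep("^(C_m|g_)", names(vals), value = TRUE)
  neg <- cond[unlist(vals[cond]) < 0]
  if (length(neg)) stop("negative conductance: ", paste(neg, collapse = ", "))
  vals
}

#' Write a flat configuration file
#'
#' @param values named list of parameter values (any subset of the schema).
#' @param path output YAML file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(values, path) {
  schema <- config_schema()
  unknown <- setdiff(names(values), names(schema))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  out <- lapply(names(values), function(nm)
    list(value = values[[nm]], unit = schema[[nm]][[2]]))
  names(out) <- names(values)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build parameter bundles from a flat configuration
#'
#' @param config named list from [load_config()].
#' @param cell_type "PC" or "IN".
#' @return A [neuron_params()] bundle.
#' @export
params_from_config <- function(config = load_config(), cell_type = "PC") {
  cell <- cell_params(cell_type, C_m = config$C_m, g_Na = config$g_Na,
                      g_K = config$g_K,
                      g_AHP = if (cell_type == "PC") config$g_AHP else 0,
                      g_KL = config$g_KL, g_NaL = config$g_NaL,
                      g_ClL = config$g_ClL, phi = config$phi,
                      g_Ca = config$g_Ca, E_Ca = config$E_Ca,
                      Cl_i = config$Cl_i, Cl_o = config$Cl_o)
  env <- microenv_params(rho = config$rho, G_glia = config$G_glia,
                         eps = config$eps, K_bath = config$K_bath,
                         beta_vol = config$beta_vol, gamma = config$gamma,
                         delta = config$delta, therm_mV = config$therm_mV)
  neuron_params(cell, env)
}

#' Flatten parameter bundles back to a configuration list
#'
#' Inverse of [params_from_config()]; a config -> params -> config round
#' trip preserves every value.
#'
#' @param params a [neuron_params()] bundle.
#' @param syn optional [synapse_params()] to include.
#' @return Named list of configuration values.
#' @export
config_from_params <- function(params, syn = NULL) {
  out <- c(params$cell[setdiff(names(params$cell), c("cell_type", "I_stim"))],
           params$env)
  if (!is.null(syn)) out <- c(out, unclass(syn))
  out[names(out) %in% names(config_schema())]
}

#' Run manifest
#'
#' Collects everything needed to re-execute a run: configuration echo,
#' seeds, package version, and input/output digests (file sizes and
#' checksums of the numeric contents).
#'
#' @param config named list of configuration values.
#' @param seeds named integer vector of seeds used.
#' @param files character vector of input/output paths (optional).
#' @return A list of class \code{"run_manifest"}.
#' @export
run_manifest <- function(config = list(), seeds = integer(), files = character()) {
  digests <- if (length(files)) {
    vapply(files, function(f)
      if (file.exists(f)) sprintf("%d bytes, sum %d", file.size(f),
                                  sum(utf8ToInt(paste(readLines(f), collapse = "")) %% 1e6))
      else "missing", character(1))
  } else character(0)
  structure(list(config = config, seeds = as.list(seeds),
                 package_version = as.character(packageVersion("neurokf")),
                 r_version = R.version.string,
                 created = format(Sys.time(), tz = "UTC", usetz = TRUE),
                 files = as.list(digests)),
            class = "run_manifest")
}

#' Write a manifest as YAML
#' @param manifest a [run_manifest()] object.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
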