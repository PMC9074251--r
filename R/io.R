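#' Read and write tie-line CSV files
#'
#' Tie-lines are exchanged as plain CSV with columns `T_K`,
#' `x1_org..xN_org`, `x1_aq..xN_aq`, one row per tie-line, component
#' order taken from the component set.
#'
#' @param dataset A [tieline_dataset()] (or a plain list of
#'   [tie_line()]s plus `components`).
#' @param path File path.
#' @param tielines List of tie-lines (for the list interface).
#' @param components A [component_set()]; on read, used for dimension
#'   checking (optional: inferred from the header when absent).
#' @param noise_sd Stated measurement uncertainty recorded in the
#'   returned dataset.
#' @return `read_tielines_csv()` returns a [tieline_dataset()];
#'   `write_tielines_csv()` returns `path` invisibly.
#' @name tieline-io
NULL

#' @rdname tieline-io
#' @export
write_tielines_csv <- function(dataset, path, tielines = NULL,
                               components = NULL) {
  if (inherits(dataset, "tieline_dataset")) {
    tielines <- dataset$tielines
    components <- dataset$components
  }
  n <- length(components$names)
  rows <- lapply(tielines, function(tl)
    c(tl$T, tl$x_org, tl$x_aq))
  df <- as.data.frame(do.call(rbind, rows))
  names(df) <- c("T_K", paste0("x", seq_len(n), "_org"),
                 paste0("x", seq_len(n), "_aq"))
  # full double precision so write/read round-trips bitwise
  df[] <- lapply(df, function(col) format(col, digits = 17))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname tieline-io
#' @export
read_tielines_csv <- function(path, components = NULL, noise_sd = 0.003) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("tie-line file '", path, "' contains no rows")
  org_cols <- grep("^x[0-9]+_org$", names(df), value = TRUE)
  aq_cols <- grep("^x[0-9]+_aq$", names(df), value = TRUE)
  if (!("T_K" %in% names(df)) || !length(org_cols) ||
      length(org_cols) != length(aq_cols))
    stop("tie-line file '", path,
         "' must have columns T_K, x1_org..xN_org, x1_aq..xN_aq")
  n <- length(org_cols)
  org_cols <- paste0("x", seq_len(n), "_org")
  aq_cols <- paste0("x", seq_len(n), "_aq")
  if (is.null(components))
    components <- component_set(paste0("component_", seq_len(n)))
  if (length(components$names) != n)
    stop("tie-line file has ", n, " components but the component set has ",
         length(components$names))
  tls <- lapply(seq_len(nrow(df)), function(r) {
    x_org <- as.numeric(df[r, org_cols])
    x_aq <- as.numeric(df[r, aq_cols])
    if (anyNA(c(x_org, x_aq, df$T_K[r])))
      stop("row ", r, " of '", path, "' contains missing values")
    tryCatch(tie_line(x_org, x_aq, df$T_K[r]),
             error = function(e) stop("row ", r, " of '", path, "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  tieline_dataset(components, tls, noise_sd = noise_sd)
}

#' Read and write NRTL parameter files (JSON or YAML)
#'
#' The on-disk schema is pairwise:
#' `{components: [...], T_ref_K: 298.15,`
#' `pairs: [{i, j, tau_ij, tau_ji, alpha}, ...]}`
#' with `i`, `j` component names. Pairs absent from the file default to
#' the ideal mixture (`tau = 0`, `alpha = 0.3`) with a warning, so that
#' partially parameterized multicomponent systems remain usable.
#'
#' @param params An [nrtl_params()] object.
#' @param path File path; the extension (`.json`, `.yaml`/`.yml`)
#'   selects the format.
#' @param molar_mass Optional molar masses recorded on write / applied on
#'   read.
#' @return `read_params_file()` returns an [nrtl_params()] object;
#'   `write_params_file()` returns `path` invisibly.
#' @name params-io
NULL

#' @rdname params-io
#' @export
write_params_file <- function(params, path) {
  nms <- params$components$names
  n <- length(nms)
  tau <- nrtl_tau(params, params$T_ref)
  pairs <- list()
  for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
    pairs[[length(pairs) + 1L]] <- list(
      i = nms[i], j = nms[j],
      tau_ij = tau[i, j], tau_ji = tau[j, i],
      alpha = params$alpha[i, j])
  }
  obj <- list(components = nms,
              molar_mass = unname(params$components$molar_mass),
              T_ref_K = params$T_ref, pairs = pairs)
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(obj, path, precision = 17)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

#' @rdname params-io
#' @export
read_params_file <- function(path, molar_mass = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = FALSE)
  nms <- as.character(unlist(obj$components))
  if (!length(nms)) stop("parameter file '", path, "' lists no components")
  mm <- molar_mass
  if (is.null(mm) && !is.null(obj$molar_mass))
    mm <- as.numeric(unlist(obj$molar_mass))
  cs <- if (is.null(mm)) component_set(nms) else component_set(nms, mm)
  n <- length(nms)
  tau <- matrix(0, n, n)
  alpha <- matrix(0.3, n, n); diag(alpha) <- 0
  seen <- matrix(FALSE, n, n)
  for (p in obj$pairs) {
    i <- match(p$i, nms); j <- match(p$j, nms)
    if (is.na(i) || is.na(j))
      stop("parameter file pair references unknown component: ",
           p$i, "/", p$j)
    tau[i, j] <- as.numeric(p$tau_ij)
    tau[j, i] <- as.numeric(p$tau_ji)
    alpha[i, j] <- alpha[j, i] <- as.numeric(p$alpha)
    seen[i, j] <- seen[j, i] <- TRUE
  }
  missing <- !seen & upper.tri(seen)
  if (any(missing)) {
    idx <- which(missing, arr.ind = TRUE)
    warning("parameter pairs missing, defaulting to ideal (tau = 0, alpha = 0.3): ",
            paste(apply(idx, 1, function(r)
              paste0(nms[r[1]], "/", nms[r[2]])), collapse = ", "))
  }
  T_ref <- if (!is.null(obj$T_ref_K)) as.numeric(obj$T_ref_K) else 298.15
  nrtl_params(cs, tau = tau, alpha = alpha, T_ref = T_ref)
}

#' Read and write stream tables (CSV)
#'
#' Stream tables are laid out with one row per component and one column
#' per stream, plus a final `flow` row carrying each stream's total flow;
#' the `basis` attribute/column distinguishes mole (kmol/h, mole
#' fractions) from mass (kg/h, mass fractions) tables.
#'
#' @param streams Named list of [stream()] objects.
#' @param path File path.
#' @param components A [component_set()] (needed on read to order and, for
#'   mass tables, convert).
#' @param basis `"mole"` (kmol/h) or `"mass"` (kg/h; converted to molar
#'   flows using the component set's molar masses).
#' @return `read_streams_csv()` returns a named list of [stream()]s (on a
#'   molar basis); `write_streams_csv()` returns `path` invisibly.
#' @name stream-io
NULL

#' @rdname stream-io
#' @export
write_streams_csv <- function(streams, path, components) {
  nms <- components$names
  df <- data.frame(component = c(nms, "flow"))
  for (lbl in names(streams)) {
    s <- streams[[lbl]]
    flows <- align_stream(s, components)
    tot <- sum(flows)
    df[[lbl]] <- c(if (tot > 0) flows / tot else rep(0, length(nms)), tot)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname stream-io
#' @export
read_streams_csv <- function(path, components, basis = "mole") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  if (nrow(df) == 0L) stop("stream file '", path, "' contains no rows")
  if (names(df)[1] != "component")
    stop("stream file '", path, "' must have a leading 'component' column")
  flow_row <- which(df$component == "flow")
  if (length(flow_row) != 1L)
    stop("stream file '", path, "' must contain exactly one 'flow' row")
  comp_rows <- setdiff(seq_len(nrow(df)), flow_row)
  file_comps <- df$component[comp_rows]
  unknown <- setdiff(file_comps, components$names)
  if (length(unknown))
    stop("stream file '", path, "' has unknown components: ",
         paste(unknown, collapse = ", "))
  out <- list()
  for (lbl in names(df)[-1]) {
    fr <- as.numeric(df[[lbl]][comp_rows])
    tot <- as.numeric(df[[lbl]][flow_row])
    if (anyNA(c(fr, tot)))
      stop("stream '", lbl, "' in '", path, "' contains missing values")
    if (any(fr < 0) || tot < 0)
      stop("stream '", lbl, "' in '", path, "' has negative entries")
    ssum <- sum(fr)
    if (ssum > 0 && abs(ssum - 1) > 5e-4)
      stop("stream '", lbl, "' fractions sum to ", format(ssum),
           ", not 1 (tolerance 5e-4)")
    fr <- stats::setNames(fr, file_comps)
    if (basis == "mass") {
      flows_mass <- fr * tot                       # kg/h per component
      mm <- components$molar_mass[file_comps]
      if (anyNA(mm)) stop("molar masses required to read a mass-basis table")
      flows <- flows_mass / mm                     # kmol/h
    } else {
      flows <- fr / max(ssum, .Machine$double.eps) * tot
      if (ssum == 0) flows <- fr * 0
    }
    out[[lbl]] <- stream(flows, lbl)
  }
  out
}

#' Read and write cost tables (YAML or CSV)
#'
#' YAML schema: `investment:` and `utility:` name/amount maps plus
#' `payout_years` and `hours_per_year`. CSV schema: columns `category`
#' (investment/utility), `item`, `amount`, with payout/hours as optional
#' `meta` rows.
#'
#' @param table A [cost_table()].
#' @param path File path; extension selects the format.
#' @return `read_cost_file()` returns a [cost_table()];
#'   `write_cost_file()` returns `path` invisibly.
#' @name cost-io
NULL

#' @rdname cost-io
#' @export
write_cost_file <- function(table, path) {
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(list(
      investment = as.list(table$investment_items),
      utility = as.list(table$utility_items),
      payout_years = table$payout_years,
      hours_per_year = table$hours_per_year), path)
  } else {
    df <- rbind(
      data.frame(category = "investment",
                 item = names(table$investment_items),
                 amount = as.numeric(table$investment_items)),
      data.frame(category = "utility",
                 item = names(table$utility_items),
                 amount = as.numeric(table$utility_items)),
      data.frame(category = "meta", item = "payout_years",
                 amount = table$payout_years),
      data.frame(category = "meta", item = "hours_per_year",
                 amount = table$hours_per_year))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname cost-io
#' @export
read_cost_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    obj <- yaml::read_yaml(path)
    cost_table(unlist(obj$investment), unlist(obj$utility),
               payout_years = obj$payout_years %||% 5,
               hours_per_year = obj$hours_per_year %||% 8000)
  } else {
    df <- utils::read.csv(path)
    need <- c("category", "item", "amount")
    if (!all(need %in% names(df)))
      stop("cost CSV '", path, "' must have columns ",
           paste(need, collapse = ", "))
    inv <- df[df$category == "investment", ]
    uti <- df[df$category == "utility", ]
    meta <- df[df$category == "meta", ]
    gv <- function(key, default) {
      v <- meta$amount[meta$item == key]
      if (length(v)) as.numeric(v[1]) else default
    }
    cost_table(stats::setNames(inv$amount, inv$item),
               stats::setNames(uti$amount, uti$item),
               payout_years = gv("payout_years", 5),
               hours_per_year = gv("hours_per_year", 8000))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
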