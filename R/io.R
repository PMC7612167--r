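#' Read a search configuration file
#'
#' Reads a YAML or JSON file (by extension) describing a testing frame and
#' search bounds.  Recognised keys: \code{p0}, \code{p1} (required),
#' \code{alpha}, \code{beta}, \code{block}, \code{max_n}, \code{r_range},
#' \code{theta_f_max}, \code{theta_e_min}, \code{max_combos}.  Omitted
#' keys take the package defaults (\code{alpha} 0.15, \code{beta} 0.2,
#' \code{block} 1, \code{max_n} 120, \code{theta_f_max} = \code{p1},
#' \code{theta_e_min} 0.7, \code{max_combos} 1e6).
#'
#' @param path configuration file path (\code{.yaml}/\code{.yml} or
#'   \code{.json}).
#' @return List with elements \code{context}
#'   (\code{\link{design_context}}) and \code{cfg}
#'   (\code{\link{search_config}}).
#' @export
read_design_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("unsupported config format '", ext,
                     "' (use .yaml or .json): ", path))
  known <- c("p0", "p1", "alpha", "beta", "block", "max_n", "r_range",
             "theta_f_max", "theta_e_min", "max_combos", "n_values")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (key in c("p0", "p1"))
    if (is.null(raw[[key]]))
      stop("config is missing required key '", key, "': ", path)
  context <- design_context(p0 = raw$p0, p1 = raw$p1,
                            alpha = raw$alpha %||% 0.15,
                            beta = raw$beta %||% 0.2)
  cfg <- search_config(max_n = raw$max_n %||% 120,
                       block = raw$block %||% 1,
                       r_range = raw$r_range,
                       theta_f_max = raw$theta_f_max,
                       theta_e_min = raw$theta_e_min %||% 0.7,
                       max_combos = raw$max_combos %||% 1e6,
                       n_values = raw$n_values)
  list(context = context, cfg = cfg)
}

#' Write a search configuration file
#'
#' Inverse of \code{\link{read_design_config}}; round-trips exactly.
#'
#' @param context a \code{\link{design_context}}.
#' @param cfg a \code{\link{search_config}}.
#' @param path output path (\code{.yaml}/\code{.yml} or \code{.json}).
#' @return \code{path}, invisibly.
#' @export
write_design_config <- function(context, cfg, path) {
  x <- list(p0 = context$p0, p1 = context$p1, alpha = context$alpha,
            beta = context$beta, block = cfg$block, max_n = cfg$max_n,
            r_range = cfg$r_range, theta_f_max = cfg$theta_f_max,
            theta_e_min = cfg$theta_e_min, max_combos = cfg$max_combos,
            n_values = cfg$n_values)
  x <- x[!vapply(x, is.null, logical(1L))]
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         yaml = , yml = yaml::write_yaml(x, path),
         json = jsonlite::write_json(x, path, auto_unbox = TRUE,
                                     digits = I(17)),
         stop("unsupported config format '", ext, "'"))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

design_table_cols <- c("design_type", "r1", "n1", "r", "n_arm", "n",
                       "ess00", "ess01", "alpha_star", "power",
                       "theta_f", "theta_e", "min_stop", "label")

#' Write / read a design table
#'
#' Serialises a set of evaluated designs (an
#' \code{\link{find_admissible}} result, a
#' \code{\link{comparator_admissible}} result, or any data frame with a
#' compatible subset of columns) to CSV with the standard column layout
#' \code{design_type, r1, n1, r, n_arm, n, ess00, ess01, alpha_star,
#' power, theta_f, theta_e, min_stop, label}.  Missing columns are written
#' as \code{NA}; the round-trip through \code{read_design_table} is
#' lossless.  Block-design rows carry \code{design_type = "block"}.
#'
#' @param designs data frame of designs.
#' @param path CSV file path.
#' @return \code{write_design_table}: \code{path}, invisibly;
#'   \code{read_design_table}: the data frame (zero rows for a
#'   header-only file).
#' @export
write_design_table <- function(designs, path) {
  stopifnot(is.data.frame(designs))
  df <- as.data.frame(designs)
  if (is.null(df$design_type) && nrow(df)) df$design_type <- "block"
  for (cc in design_table_cols)
    if (is.null(df[[cc]])) df[[cc]] <- rep(NA, nrow(df))
  df <- df[, design_table_cols, drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_table
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("design table not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(design_table_cols, names(df))
  if (length(missing))
    stop("design table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Write / read a single design as JSON
#'
#' \code{\link{block_design}} and \code{\link{two_stage_design}} objects
#' round-trip losslessly (thresholds at full double precision).
#'
#' @param design the design object.
#' @param path JSON file path.
#' @return \code{write_design_json}: \code{path}, invisibly;
#'   \code{read_design_json}: the design object.
#' @export
write_design_json <- function(design, path) {
  if (inherits(design, "block_design")) {
    ctx <- design$context
    x <- list(design_type = "block", r = design$r, n = design$n,
              block = design$block, theta_f = design$theta_f,
              theta_e = design$theta_e, p0 = ctx$p0, p1 = ctx$p1,
              alpha = ctx$alpha, beta = ctx$beta)
  } else if (inherits(design, "two_stage_design")) {
    x <- list(design_type = design$type, r1 = design$r1, n1 = design$n1,
              r = design$r, n_arm = design$n_arm)
  } else stop("'design' must be a block_design or two_stage_design")
  # digits = I(17): thresholds must survive the round trip bit-for-bit,
  # since state classification compares against them exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_design_json
#' @export
read_design_json <- function(path) {
  if (!file.exists(path)) stop("design file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(x$design_type)) stop("design file lacks 'design_type': ", path)
  if (x$design_type == "block") {
    for (key in c("r", "n", "block", "theta_f", "theta_e", "p0", "p1"))
      if (is.null(x[[key]]))
        stop("block design file is missing key '", key, "': ", path)
    block_design(r = x$r, n = x$n, block = x$block, theta_f = x$theta_f,
                 theta_e = x$theta_e, p0 = x$p0, p1 = x$p1,
                 alpha = x$alpha %||% 0.15, beta = x$beta %||% 0.2)
  } else {
    for (key in c("r1", "n1", "r", "n_arm"))
      if (is.null(x[[key]]))
        stop("two-stage design file is missing key '", key, "': ", path)
    two_stage_design(x$design_type, x$r1, x$n1, x$r, x$n_arm)
  }
}
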