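# Pipeline configuration: defaults, loading (JSON or a YAML subset),
# schema validation with unknown-key rejection.

#' Default pipeline configuration
#'
#' All detection parameters are exposed under `detection:` with the
#' H-DAB positive-cell-detection defaults; the stain matrix under `stains:`
#' (nine floats, one RGB row per stain) overrides the standard H-DAB
#' vectors. See `inst/schema/config-schema.json` for the published schema.
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = ".",
    days = c(0L, 3L, 7L, 10L),
    detection = list(pixel_size_um = 0.5, min_radius_um = 5,
                     max_radius_um = 10, splitting_threshold = 0.15,
                     cell_expansion_um = 3, dab_od_threshold = 0.15,
                     smoothing_sigma_um = 1.0, h_od_threshold = 0.1),
    stains = list(name = "H-DAB (Ruifrok-Johnson)",
                  h = c(0.651, 0.701, 0.290),
                  dab = c(0.269, 0.568, 0.778),
                  residual = NULL),
    statistics = list(posthoc_method = "bonferroni_paired_t",
                      sphericity_alpha = 0.05),
    white_point = 255
  )
}

# Minimal YAML subset: nested maps by 2-space indentation, `key: value`
# scalars, inline `[a, b, c]` lists, `#` comments. Sufficient for the
# pipeline config; JSON is the primary config format.
parse_yaml_subset <- function(lines) {
  lines <- sub("#.*$", "", lines)
  keep <- grepl("\\S", lines)
  lines <- lines[keep]
  parse_scalar <- function(s) {
    s <- trimws(s)
    if (s %in% c("null", "~", "")) return(NULL)
    if (s %in% c("true", "True")) return(TRUE)
    if (s %in% c("false", "False")) return(FALSE)
    if (grepl("^\\[.*\\]$", s)) {
      items <- strsplit(sub("^\\[", "", sub("\\]$", "", s)), ",")[[1]]
      vals <- lapply(items, parse_scalar)
      if (all(vapply(vals, is.numeric, TRUE))) return(unlist(vals))
      return(unlist(lapply(vals, as.character)))
    }
    num <- suppressWarnings(as.numeric(s))
    if (!is.na(num)) return(num)
    gsub("^[\"']|[\"']$", "", s)
  }
  parse_block <- function(idx, indent) {
    out <- list()
    i <- 1
    while (i <= length(idx)) {
      ln <- lines[idx[i]]
      this_ind <- nchar(sub("\\S.*$", "", ln))
      if (this_ind != indent) stop("bad YAML indentation at: ", trimws(ln))
      m <- regmatches(ln, regexec("^\\s*([^:]+):\\s*(.*)$", ln))[[1]]
      if (length(m) < 2) stop("cannot parse YAML line: ", ln)
      key <- trimws(m[2]); rest <- m[3]
      if (nzchar(trimws(rest))) {
        out[[key]] <- parse_scalar(rest)
        i <- i + 1
      } else {
        j <- i + 1
        child <- integer(0)
        while (j <= length(idx)) {
          ind_j <- nchar(sub("\\S.*$", "", lines[idx[j]]))
          if (ind_j <= indent) break
          child <- c(child, idx[j]); j <- j + 1
        }
        val <- if (length(child)) {
          ind_c <- nchar(sub("\\S.*$", "", lines[child[1]]))
          parse_block(child, ind_c)
        } else NULL
        out[key] <- list(val)
        i <- j
      }
    }
    out
  }
  parse_block(seq_along(lines), 0)
}

config_schema <- function() {
  list(
    seed = "number", output_dir = "string", days = "number_vector",
    white_point = "number",
    detection = list(pixel_size_um = "number", min_radius_um = "number",
                     max_radius_um = "number",
                     splitting_threshold = "number",
                     cell_expansion_um = "number",
                     dab_od_threshold = "number",
                     smoothing_sigma_um = "number",
                     h_od_threshold = "number"),
    stains = list(name = "string", h = "number_vector",
                  dab = "number_vector", residual = "number_vector"),
    statistics = list(posthoc_method = "string",
                      sphericity_alpha = "number")
  )
}

#' Validate a pipeline configuration
#'
#' Checks types against the shipped schema and rejects unknown keys.
#'
#' @param config nested list (partial configs allowed; they are merged over
#'   [default_config()] by [load_config()]).
#' @return `config`, invisibly; errors on violation.
#' @export
validate_config <- function(config) {
  check <- function(node, schema, path) {
    unknown <- setdiff(names(node), names(schema))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(path, unknown, collapse = ", "))
    for (key in names(node)) {
      v <- node[[key]]; s <- schema[[key]]
      if (is.null(v)) next
      here <- paste0(path, key)
      if (is.list(s)) {
        if (!is.list(v)) stop("config key ", here, " must be a mapping")
        check(v, s, paste0(here, "."))
      } else if (s == "number") {
        if (!is.numeric(v) || length(v) != 1)
          stop("config key ", here, " must be a single number")
      } else if (s == "number_vector") {
        if (!is.numeric(v)) stop("config key ", here, " must be numeric")
      } else if (s == "string") {
        if (!is.character(v) || length(v) != 1)
          stop("config key ", here, " must be a single string")
      }
    }
  }
  check(config, config_schema(), "")
  if (!is.null(config$statistics$posthoc_method) &&
      !config$statistics$posthoc_method %in%
        c("bonferroni_paired_t", "tukey_hsd"))
    stop("statistics.posthoc_method must be bonferroni_paired_t or tukey_hsd")
  invisible(config)
}

merge_config <- function(base, override) {
  for (key in names(override)) {
    if (is.list(override[[key]]) && is.list(base[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]])
    else base[[key]] <- override[[key]]
  }
  base
}

#' Load, merge and validate a pipeline configuration
#'
#' Reads JSON (`.json`) or a YAML subset (`.yml`/`.yaml`: nested maps,
#' scalars, inline lists), validates it against the shipped schema
#' (unknown keys rejected) and merges it over [default_config()].
#'
#' @param path config file, or `NULL` for pure defaults.
#' @return Full configuration list with attribute `"config_hash"` (md5 of
#'   the canonical JSON serialization).
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json")
      jsonlite::read_json(path, simplifyVector = TRUE)
    else if (ext %in% c("yml", "yaml"))
      parse_yaml_subset(readLines(path, warn = FALSE))
    else stop("config must be .json, .yml or .yaml")
    validate_config(user)
    cfg <- merge_config(cfg, user)
  }
  validate_config(cfg)
  ser <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(); writeLines(ser, tmp)
  attr(cfg, "config_hash") <- unname(tools::md5sum(tmp))
  unlink(tmp)
  cfg
}

config_detection_params <- function(config) {
  do.call(detection_params, config$detection)
}

config_stain_vectors <- function(config) {
  s <- config$stains
  stain_vectors(s$h, s$dab, residual = s$residual,
                name = if (is.null(s$name)) "config" else s$name)
}
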