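# Minimal TOML-subset reader: [section] headers, `key = value` pairs with
# string, number, boolean and flat-array values, `#` comments. Sufficient
# for run configuration files; not a general TOML implementation.

#' Read a configuration file (TOML subset)
#'
#' Supports `[section]` headers and `key = value` pairs where value is a
#' double-quoted string, number, `true`/`false`, or a flat array of those.
#'
#' @param path Path to the file.
#' @return Named list of sections, each a named list of values.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regexec("^([A-Za-z0-9_.-]+)[[:space:]]*=[[:space:]]*(.+)$", line)
    parts <- regmatches(line, m)[[1]]
    if (length(parts) != 3L)
      stop("config line ", i, ": cannot parse '", lines[[i]], "'")
    val <- parse_toml_value(trimws(parts[3]), i)
    if (is.null(section)) out[[parts[2]]] <- val
    else out[[section]][[parts[2]]] <- val
  }
  out
}

parse_toml_value <- function(v, line) {
  if (grepl('^".*"$', v)) return(gsub('^"|"$', "", v))
  if (v %in% c("true", "false")) return(v == "true")
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(gsub("^\\[|\\]$", "", v))
    if (!nzchar(inner)) return(list())
    items <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(items, parse_toml_value, line = line)
    if (all(vapply(vals, is.numeric, logical(1)))) return(unlist(vals))
    return(vals)
  }
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  stop("config line ", line, ": unsupported value '", v, "'")
}

# Apply a config section to a constructor's defaults, rejecting unknown keys.
apply_config_section <- function(section_values, constructor, section_name) {
  if (is.null(section_values)) return(constructor())
  known <- names(formals(constructor))
  unknown <- setdiff(names(section_values), known)
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1) "s", " in [",
         section_name, "]: ", paste(unknown, collapse = ", "))
  do.call(constructor, section_values)
}
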