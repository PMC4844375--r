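#' @title Photosynthetic network specification
#' @description
#' A `network_spec` declares, as data, which physiological variables form
#' the network and which unordered variable pairs belong to which module.
#' The default network has two modules — leaf gas exchange and PSII
#' photochemistry — joined by a single linking pair (ETR with the
#' light-saturated photosynthetic capacity) that is reported on its own and
#' enters neither module average.
#'
#' Variable names are plain ASCII column identifiers; the mapping to the
#' conventional symbols is:
#'
#' | column  | symbol      | meaning                                   |
#' |---------|-------------|-------------------------------------------|
#' | `AmaxL` | A_maxL      | light-saturated photosynthetic capacity   |
#' | `gs`    | g_s         | stomatal conductance                      |
#' | `E`     | E           | transpiration rate                        |
#' | `Rd`    | R_d         | dark (mitochondrial) respiration          |
#' | `Pr`    | Pr          | photorespiration                          |
#' | `Ci`    | C_i         | intercellular CO2 concentration           |
#' | `FvFm`  | F_v/F_m     | potential PSII quantum efficiency         |
#' | `dF_Fm` | dF/F_m'     | effective PSII quantum efficiency         |
#' | `NPQ`   | NPQ         | non-photochemical quenching               |
#' | `ETR`   | ETR         | apparent electron transport rate          |
#' @name network_spec
NULL

# Measured variables of the default network, with units.
default_variables <- function() {
  data.frame(
    name = c("AmaxL", "gs", "E", "Rd", "Pr", "Ci",
             "FvFm", "dF_Fm", "NPQ", "ETR"),
    unit = c("umol CO2 m-2 s-1", "mol H2O m-2 s-1", "mmol H2O m-2 s-1",
             "umol CO2 m-2 s-1", "umol CO2 m-2 s-1", "umol mol-1",
             "dimensionless", "dimensionless", "dimensionless",
             "umol e- m-2 s-1"),
    module_hint = c(rep("gas_exchange", 6), rep("photochemical", 4)),
    stringsAsFactors = FALSE
  )
}

# canonicalize a two-column pair data.frame: a < b lexicographically
canon_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("a", "b") %in% names(pairs)))
  a <- as.character(pairs$a)
  b <- as.character(pairs$b)
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  out <- data.frame(a = a, b = b, stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label pairs as "a-b" strings
#'
#' @param pairs data.frame with columns `a` and `b`.
#' @return character vector.
#' @export
pair_labels <- function(pairs) paste(pairs$a, pairs$b, sep = "-")

#' Construct and validate a network specification
#'
#' @param variables data.frame with columns `name`, `unit`, `module_hint`.
#' @param modules named list of pair data.frames (columns `a`, `b`).
#' @param linking pair data.frame of pairs reported separately from every
#'   module (and excluded from the global average).
#' @return An object of class `network_spec`.
#' @details Pairs are unordered; they are stored canonically with
#'   `a < b` lexicographically. Self-pairs, duplicated pairs (within or
#'   across modules and the linking set) and pairs naming undeclared
#'   variables are rejected with an error naming the offending pair.
#' @export
new_network_spec <- function(variables, modules, linking) {
  variables <- as.data.frame(variables, stringsAsFactors = FALSE)
  if (!all(c("name", "unit", "module_hint") %in% names(variables))) {
    abort("`variables` needs columns name, unit, module_hint")
  }
  if (anyDuplicated(variables$name)) {
    abort("duplicate variable name: %s",
          paste(unique(variables$name[duplicated(variables$name)]),
                collapse = ", "))
  }
  if (any(!nzchar(variables$unit))) {
    abort("empty unit for variable(s): %s",
          paste(variables$name[!nzchar(variables$unit)], collapse = ", "))
  }
  if (!is.list(modules) || is.null(names(modules)) ||
      any(!nzchar(names(modules)))) {
    abort("`modules` must be a named list of pair tables")
  }

  check_pairs <- function(pairs, where) {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (nrow(pairs) == 0) return(canon_pairs(pairs))
    self <- pairs$a == pairs$b
    if (any(self)) {
      abort("self-pair not allowed in %s: (%s, %s)", where,
            pairs$a[which(self)[1]], pairs$b[which(self)[1]])
    }
    unknown <- setdiff(c(pairs$a, pairs$b), variables$name)
    if (length(unknown)) {
      abort("unknown variable(s) in %s: %s", where,
            paste(unknown, collapse = ", "))
    }
    canon_pairs(pairs)
  }

  modules <- mapply(check_pairs, modules, paste("module", names(modules)),
                    SIMPLIFY = FALSE)
  linking <- check_pairs(linking, "linking set")

  all_lab <- c(unlist(lapply(modules, pair_labels), use.names = FALSE),
               pair_labels(linking))
  if (anyDuplicated(all_lab)) {
    abort("duplicate pair across network: %s",
          paste(unique(all_lab[duplicated(all_lab)]), collapse = ", "))
  }

  structure(list(variables = variables, modules = modules,
                 linking = linking),
            class = "network_spec")
}

#' The default photosynthetic network
#'
#' Nine gas-exchange pairs (AmaxL-gs, AmaxL-E, AmaxL-Rd, AmaxL-Pr, AmaxL-Ci,
#' Ci-gs, Ci-Rd, Ci-Pr, gs-E), six photochemical pairs (dF_Fm-ETR,
#' dF_Fm-FvFm, dF_Fm-NPQ, ETR-NPQ, FvFm-NPQ, FvFm-ETR) and the single
#' linking pair AmaxL-ETR: 16 distinct unordered pairs in total.
#'
#' @return A [new_network_spec()] object.
#' @examples
#' spec <- default_network()
#' vapply(spec$modules, nrow, integer(1))  # 9 and 6
#' @export
default_network <- function() {
  ge <- data.frame(
    a = c("AmaxL", "AmaxL", "AmaxL", "AmaxL", "AmaxL", "Ci", "Ci", "Ci", "gs"),
    b = c("gs",    "E",     "Rd",    "Pr",    "Ci",    "gs", "Rd", "Pr", "E"),
    stringsAsFactors = FALSE
  )
  pho <- data.frame(
    a = c("dF_Fm", "dF_Fm", "dF_Fm", "ETR", "FvFm", "FvFm"),
    b = c("ETR",   "FvFm",  "NPQ",   "NPQ", "NPQ",  "ETR"),
    stringsAsFactors = FALSE
  )
  link <- data.frame(a = "ETR", b = "AmaxL", stringsAsFactors = FALSE)
  new_network_spec(default_variables(),
                   list(gas_exchange = ge, photochemical = pho),
                   link)
}

#' Read a network specification from a YAML config
#'
#' The config declares `variables` (list of `name`/`unit`/`module_hint`
#' records), `modules` (named lists of two-element `[a, b]` pairs) and
#' `linking` (list of pairs). [write_network()] is its inverse;
#' `load_network(write_network(spec))` reproduces `spec`.
#'
#' @param path path to a YAML file, or `NULL` when `text` is given.
#' @param text YAML source as a string (alternative to `path`).
#' @return A validated [new_network_spec()] object.
#' @export
load_network <- function(path = NULL, text = NULL) {
  if (is.null(path) == is.null(text)) {
    abort("supply exactly one of `path` or `text`")
  }
  cfg <- if (is.null(text)) yaml::read_yaml(path) else
    yaml::yaml.load(text)
  for (fld in c("variables", "modules", "linking")) {
    if (is.null(cfg[[fld]])) abort("config is missing section '%s'", fld)
  }
  vars <- do.call(rbind, lapply(cfg$variables, function(v) {
    data.frame(name = v$name %||% abort("variable without a name"),
               unit = v$unit %||% "",
               module_hint = v$module_hint %||% "other",
               stringsAsFactors = FALSE)
  }))
  as_pairs <- function(lst, where) {
    if (length(lst) == 0) {
      return(data.frame(a = character(), b = character()))
    }
    bad <- !vapply(lst, function(p) length(p) == 2L, logical(1))
    if (any(bad)) abort("malformed pair in %s (need [a, b])", where)
    # reject duplicates as written, before canonicalization folds them
    lab <- vapply(lst, function(p) paste(sort(unlist(p)), collapse = "-"),
                  character(1))
    if (anyDuplicated(lab)) {
      abort("duplicate pair in %s: %s", where,
            paste(unique(lab[duplicated(lab)]), collapse = ", "))
    }
    data.frame(a = vapply(lst, function(p) as.character(p[[1]]), ""),
               b = vapply(lst, function(p) as.character(p[[2]]), ""),
               stringsAsFactors = FALSE)
  }
  modules <- lapply(seq_along(cfg$modules), function(i) {
    as_pairs(cfg$modules[[i]], paste("module", names(cfg$modules)[i]))
  })
  names(modules) <- names(cfg$modules)
  new_network_spec(vars, modules, as_pairs(cfg$linking, "linking"))
}

#' Serialize a network specification to YAML
#'
#' @param spec a [new_network_spec()] object.
#' @param path optional file to write; with `path = NULL` the YAML text is
#'   returned invisibly-visible as a string.
#' @return YAML string (invisibly when written to `path`).
#' @export
write_network <- function(spec, path = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  to_list <- function(pairs) {
    lapply(seq_len(nrow(pairs)), function(i) c(pairs$a[i], pairs$b[i]))
  }
  cfg <- list(
    variables = lapply(seq_len(nrow(spec$variables)), function(i) {
      as.list(spec$variables[i, c("name", "unit", "module_hint")])
    }),
    modules = lapply(spec$modules, to_list),
    linking = to_list(spec$linking)
  )
  txt <- yaml::as.yaml(cfg)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec>", nrow(x$variables), "variables\n")
  for (m in names(x$modules)) {
    cat(sprintf("  %s (%d pairs): %s\n", m, nrow(x$modules[[m]]),
                paste(pair_labels(x$modules[[m]]), collapse = ", ")))
  }
  cat("  linking:", paste(pair_labels(x$linking), collapse = ", "), "\n")
  invisible(x)
}

#' All pairs of a network spec with their module membership
#'
#' @param spec a [new_network_spec()] object.
#' @return data.frame with columns `a`, `b`, `module` (linking pairs get
#'   module `"linking"`).
#' @export
spec_all_pairs <- function(spec) {
  rows <- lapply(names(spec$modules), function(m) {
    cbind(spec$modules[[m]], module = m, stringsAsFactors = FALSE)
  })
  link <- spec$linking
  if (nrow(link)) link <- cbind(link, module = "linking",
                                stringsAsFactors = FALSE)
  do.call(rbind, c(rows, list(link)))
}
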