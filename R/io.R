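#' @keywords internal
write_atomic <- function(writer, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

write_lines_atomic <- function(lines, path) {
  write_atomic(function(tmp) writeLines(lines, tmp), path)
}

write_json_atomic <- function(x, path) {
  write_atomic(function(tmp) {
    jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }, path)
}

write_csv_atomic <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.csv(df, tmp, row.names = FALSE, quote = TRUE,
                     fileEncoding = "UTF-8")
  }, path)
}

#' Write a gem bundle to disk
#'
#' Serialises a synthetic gem as plain text: `network.tsv` (reaction
#' table), `medium.txt` (one base-medium metabolite per line),
#' `costs.tsv` (`nutrient <TAB> normalised cost`), and `manifest.json`
#' (essential set, target annotation, orderings, seed, parameters). All
#' writes are atomic (write-then-rename).
#'
#' @param gem a [generate_gem()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_gem_bundle <- function(gem, dir) {
  stopifnot(inherits(gem, "synthetic_gem"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_lines_atomic(format_network_tsv(gem$network),
                     file.path(dir, "network.tsv"))
  write_lines_atomic(gem$base_medium, file.path(dir, "medium.txt"))
  cost_lines <- if (length(gem$nutrients) > 0L) {
    sprintf("%s\t%.12g", names(gem$nutrients), unname(gem$nutrients))
  } else {
    character()
  }
  write_lines_atomic(cost_lines, file.path(dir, "costs.tsv"))
  write_json_atomic(list(
    essential = gem$essential,
    target = gem$target,
    metabolites = gem$network$metabolites,
    genes = gem$network$genes,
    seed = gem$seed,
    params = gem$params
  ), file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Read a gem bundle from disk
#'
#' Inverse of [write_gem_bundle()]; metabolite and gene orderings are
#' restored from the manifest so the round trip is exact.
#'
#' @param dir bundle directory.
#' @return a `synthetic_gem`.
#' @export
read_gem_bundle <- function(dir) {
  need <- file.path(dir, c("network.tsv", "medium.txt", "costs.tsv",
                           "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing) > 0L) {
    stop("gem bundle incomplete, missing: ",
         paste(basename(missing), collapse = ", "), call. = FALSE)
  }
  man <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  lines <- readLines(file.path(dir, "network.tsv"))
  reactions <- lapply(strsplit(lines, "\t", fixed = TRUE), function(f) {
    if (length(f) == 3L) f <- c(f, "")
    split_ids <- function(s) {
      s <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
      s[nzchar(s)]
    }
    list(id = f[[1L]], reactants = split_ids(f[[2L]]),
         products = split_ids(f[[3L]]), rule = parse_gpr(f[[4L]]))
  })
  net <- metabolic_network(reactions, metabolites = man$metabolites,
                           genes = man$genes)
  cost_lines <- readLines(file.path(dir, "costs.tsv"))
  cost_lines <- cost_lines[nzchar(trimws(cost_lines))]
  nutrients <- numeric(0L)
  if (length(cost_lines) > 0L) {
    parts <- strsplit(cost_lines, "\t", fixed = TRUE)
    nutrients <- vapply(parts, function(f) as.numeric(f[[2L]]), numeric(1L))
    names(nutrients) <- vapply(parts, `[[`, character(1L), 1L)
  }
  structure(list(
    network = net,
    base_medium = readLines(file.path(dir, "medium.txt")),
    nutrients = nutrients,
    essential = man$essential,
    target = list(reaction = man$target$reaction,
                  genes = man$target$genes, mode = man$target$mode),
    seed = as.integer(man$seed),
    params = do.call(gem_params, man$params)
  ), class = "synthetic_gem")
}

#' Read a medium file (one metabolite id per line)
#'
#' @param path file path; `#` comments and blank lines skipped.
#' @return character vector of metabolite ids.
#' @export
read_medium_file <- function(path) {
  lines <- trimws(readLines(path))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a nutrient cost TSV (`nutrient <TAB> cost`)
#'
#' @param path file path.
#' @return named numeric cost vector.
#' @export
read_cost_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(numeric(0L))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  costs <- vapply(parts, function(f) {
    if (length(f) < 2L) stop("malformed cost line: ", paste(f, collapse = " "),
                             call. = FALSE)
    v <- suppressWarnings(as.numeric(f[[2L]]))
    if (is.na(v) || v < 0) stop("invalid cost for ", f[[1L]], call. = FALSE)
    v
  }, numeric(1L))
  names(costs) <- vapply(parts, `[[`, character(1L), 1L)
  costs
}

#' Parse datalog reaction facts
#'
#' Reads lines of the form `reaction(a,b).` into an edge list; used by
#' the `closure` command, whose answers are `pathway/2` facts.
#'
#' @param lines character vector of fact lines (blank lines and `%`
#'   comments skipped).
#' @return data.frame with columns `from`, `to`.
#' @export
parse_reaction_facts <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "%")]
  from <- character(length(lines))
  to <- character(length(lines))
  for (i in seq_along(lines)) {
    m <- regmatches(lines[[i]],
                    regexec("^reaction\\(([^,()]+),([^,()]+)\\)\\.$",
                            lines[[i]]))[[1L]]
    if (length(m) != 3L) {
      stop("line ", i, ": expected 'reaction(a,b).', got '", lines[[i]], "'",
           call. = FALSE)
    }
    from[[i]] <- trimws(m[[2L]])
    to[[i]] <- trimws(m[[3L]])
  }
  data.frame(from = from, to = to, stringsAsFactors = FALSE)
}

#' Transitive closure of reaction facts as pathway facts
#'
#' @param facts data.frame from [parse_reaction_facts()].
#' @return sorted character vector of `pathway(a,b).` lines.
#' @export
pathway_facts <- function(facts) {
  if (nrow(facts) == 0L) return(character())
  nodes <- sort(unique(c(facts$from, facts$to)))
  R <- matrix(0L, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  R[cbind(match(facts$from, nodes), match(facts$to, nodes))] <- 1L
  cl <- transitive_closure(R)
  idx <- which(cl == 1L, arr.ind = TRUE)
  sort(sprintf("pathway(%s,%s).", nodes[idx[, 1L]], nodes[idx[, 2L]]))
}
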