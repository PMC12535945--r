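#' Metabolic networks with gene-reaction rules
#'
#' A `metabolic_network` is the background knowledge of the whole stack: an
#' ordered metabolite list, an ordered gene list, and an ordered list of
#' directed reactions. Each reaction consumes a (possibly empty) reactant
#' set and produces a non-empty product set, gated by a [gpr] rule.
#' Orderings are fixed at construction (first appearance, or document
#' order on import) so that every matrix index is deterministic.
#'
#' @param reactions list of reaction descriptions, each a list with fields
#'   `id` (string), `reactants` (character vector of metabolite ids, may
#'   be empty), `products` (non-empty character vector) and `rule`
#'   (a `gpr_rule` or a rule string understood by [parse_gpr()]).
#' @param metabolites optional character vector fixing the metabolite
#'   ordering; ids encountered in reactions but absent here are appended
#'   in order of first appearance.
#' @param genes optional character vector fixing the gene ordering, same
#'   append semantics.
#' @return an object of class `metabolic_network` with fields
#'   `metabolites`, `genes` and `reactions` (reactant/product sets stored
#'   as integer indices into `metabolites`).
#' @export
metabolic_network <- function(reactions, metabolites = character(),
                              genes = character()) {
  stopifnot(is.list(reactions))
  mets <- as.character(metabolites)
  gns <- as.character(genes)
  if (anyDuplicated(mets)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(gns)) stop("duplicate gene ids", call. = FALSE)

  rxn_ids <- vapply(reactions, function(r) as.character(r$id), character(1L))
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction id: ", rxn_ids[duplicated(rxn_ids)][1L],
         call. = FALSE)
  }

  # pass 1: fix orderings by first appearance
  for (r in reactions) {
    for (m in c(r$reactants, r$products)) {
      if (!(m %in% mets)) mets <- c(mets, m)
    }
  }
  parsed <- lapply(reactions, function(r) {
    rule <- r$rule
    if (!is_gpr_rule(rule)) rule <- parse_gpr(as.character(rule))
    rule
  })
  for (rule in parsed) {
    for (g in gpr_genes(rule)) if (!(g %in% gns)) gns <- c(gns, g)
  }

  # pass 2: index
  rxns <- vector("list", length(reactions))
  for (k in seq_along(reactions)) {
    r <- reactions[[k]]
    products <- unique(as.character(r$products))
    if (length(products) == 0L) {
      stop("reaction ", r$id, ": empty product set", call. = FALSE)
    }
    rxns[[k]] <- list(
      id = as.character(r$id),
      reactants = match(unique(as.character(r$reactants)), mets),
      products = match(products, mets),
      rule = parsed[[k]]
    )
  }

  structure(list(metabolites = mets, genes = gns, reactions = rxns),
            class = "metabolic_network")
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d genes, %d reactions\n",
              length(x$metabolites), length(x$genes), length(x$reactions)))
  invisible(x)
}

n_metabolites <- function(net) length(net$metabolites)
n_reactions <- function(net) length(net$reactions)
reaction_ids <- function(net) vapply(net$reactions, `[[`, character(1L), "id")

#' Parse a network from reaction-table TSV text
#'
#' One reaction per line:
#' `reaction_id <TAB> comma-separated reactants <TAB> comma-separated
#' products <TAB> rule-string`. Lines starting with `#` and blank lines
#' are skipped. An empty rule field means a spontaneous reaction; `?`
#' marks a masked rule. Metabolite and gene orderings follow first
#' appearance.
#'
#' @param text a single string (possibly multi-line) or a character
#'   vector of lines.
#' @return a [metabolic_network()].
#' @export
#' @examples
#' net <- parse_network_tsv("R1\ta,b\tc\tg1 or g2")
parse_network_tsv <- function(text) {
  lines <- if (length(text) == 1L && grepl("\n", text)) {
    strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    as.character(text)
  }
  reactions <- list()
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line)) || startsWith(trimws(line), "#")) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L || length(fields) > 4L) {
      stop("line ", i, ": expected 4 tab-separated fields, got ",
           length(fields), call. = FALSE)
    }
    if (length(fields) == 3L) fields <- c(fields, "")  # trailing empty rule
    split_ids <- function(s) {
      s <- trimws(strsplit(s, ",", fixed = TRUE)[[1L]])
      s[nzchar(s)]
    }
    rule <- tryCatch(parse_gpr(fields[[4L]]), error = function(e) {
      stop("line ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    reactions[[length(reactions) + 1L]] <- list(
      id = trimws(fields[[1L]]),
      reactants = split_ids(fields[[2L]]),
      products = split_ids(fields[[3L]]),
      rule = rule
    )
  }
  metabolic_network(reactions)
}

#' Serialize a network to reaction-table TSV text
#'
#' Inverse of [parse_network_tsv()] up to whitespace; deterministic for a
#' fixed network (used for byte-stable fixture bundles).
#'
#' @param net a [metabolic_network()].
#' @return a character vector of TSV lines.
#' @export
format_network_tsv <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  vapply(net$reactions, function(r) {
    paste(r$id,
          paste(net$metabolites[r$reactants], collapse = ","),
          paste(net$metabolites[r$products], collapse = ","),
          format(r$rule),
          sep = "\t")
  }, character(1L))
}

#' Import a BiGG-style GEM JSON document
#'
#' Accepts the parsed JSON structure of a BiGG genome-scale model
#' (`metabolites`, `reactions` with per-metabolite stoichiometric
#' coefficients, `gene_reaction_rule` strings and flux bounds).
#' Stoichiometry is reduced to presence/absence: negative-coefficient
#' metabolites become reactants, positive ones products. A reaction with
#' a negative lower flux bound is reversible and is expanded into two
#' directed reactions (`_fwd`/`_rev`) sharing the rule. An empty
#' `gene_reaction_rule` becomes spontaneous. Metabolite ordering follows
#' document order.
#'
#' @param document a list as returned by
#'   `jsonlite::fromJSON(..., simplifyVector = FALSE)`, or a path to a
#'   JSON file.
#' @return a [metabolic_network()].
#' @export
import_bigg_json <- function(document) {
  if (is.character(document) && length(document) == 1L) {
    document <- jsonlite::fromJSON(document, simplifyVector = FALSE)
  }
  for (key in c("metabolites", "reactions")) {
    if (is.null(document[[key]])) {
      stop("GEM-JSON import error: missing key '", key, "'", call. = FALSE)
    }
  }
  met_order <- vapply(document$metabolites, function(m) {
    if (is.null(m$id)) stop("GEM-JSON import error: missing key 'id' in metabolites",
                            call. = FALSE)
    as.character(m$id)
  }, character(1L))
  gene_order <- if (!is.null(document$genes)) {
    vapply(document$genes, function(g) as.character(g$id), character(1L))
  } else {
    character()
  }

  reactions <- list()
  for (rx in document$reactions) {
    for (key in c("id", "metabolites")) {
      if (is.null(rx[[key]])) {
        stop("GEM-JSON import error: missing key '", key, "' in reactions",
             call. = FALSE)
      }
    }
    coefs <- unlist(rx$metabolites)
    reactants <- names(coefs)[coefs < 0]
    products <- names(coefs)[coefs > 0]
    rule <- if (is.null(rx$gene_reaction_rule) || !nzchar(trimws(rx$gene_reaction_rule))) {
      gpr_spontaneous()
    } else {
      parse_gpr(rx$gene_reaction_rule)
    }
    lb <- if (is.null(rx$lower_bound)) 0 else rx$lower_bound
    reversible <- lb < 0
    if (reversible) {
      reactions[[length(reactions) + 1L]] <-
        list(id = paste0(rx$id, "_fwd"), reactants = reactants,
             products = products, rule = rule)
      reactions[[length(reactions) + 1L]] <-
        list(id = paste0(rx$id, "_rev"), reactants = products,
             products = reactants, rule = rule)
    } else {
      reactions[[length(reactions) + 1L]] <-
        list(id = rx$id, reactants = reactants, products = products,
             rule = rule)
    }
  }
  metabolic_network(reactions, metabolites = met_order, genes = gene_order)
}

#' Encode a network as reactant/product Boolean matrices
#'
#' Returns the pair (R1, R2) of 0/1 matrices of shape
#' (#reactions x #metabolites): `R1[j, i] = 1` iff metabolite `i` is a
#' reactant of reaction `j`, and `R2[j, i] = 1` iff it is a product.
#' Together with a source vector these matrices drive [bmlp_ie()].
#'
#' @param net a [metabolic_network()].
#' @return list with elements `R1` and `R2` (integer 0/1 matrices with
#'   dimnames reaction x metabolite).
#' @export
encode_matrices <- function(net) {
  stopifnot(inherits(net, "metabolic_network"))
  nr <- n_reactions(net)
  nm <- n_metabolites(net)
  dn <- list(reaction_ids(net), net$metabolites)
  R1 <- matrix(0L, nr, nm, dimnames = dn)
  R2 <- matrix(0L, nr, nm, dimnames = dn)
  for (j in seq_len(nr)) {
    R1[j, net$reactions[[j]]$reactants] <- 1L
    R2[j, net$reactions[[j]]$products] <- 1L
  }
  list(R1 = R1, R2 = R2)
}

#' Decode (R1, R2) matrices back into reactant/product id sets
#'
#' Round-trip companion of [encode_matrices()], mainly for testing the
#' encoding is lossless.
#'
#' @param R1,R2 matrices as produced by [encode_matrices()].
#' @return list of per-reaction lists with `reactants` and `products`
#'   character vectors.
#' @export
decode_matrices <- function(R1, R2) {
  stopifnot(identical(dim(R1), dim(R2)))
  mets <- colnames(R1)
  lapply(seq_len(nrow(R1)), function(j) {
    list(reactants = mets[R1[j, ] == 1L], products = mets[R2[j, ] == 1L])
  })
}

#' Source-metabolite vector for a growth medium
#'
#' @param net a [metabolic_network()].
#' @param medium character vector of metabolite ids initially available.
#' @return named integer 0/1 vector over the network's metabolites.
#' @export
medium_vector <- function(net, medium) {
  stopifnot(inherits(net, "metabolic_network"))
  medium <- unique(as.character(medium))
  unknown <- setdiff(medium, net$metabolites)
  if (length(unknown) > 0L) {
    stop("unknown metabolite id(s) in medium: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  v <- integer(n_metabolites(net))
  names(v) <- net$metabolites
  v[medium] <- 1L
  v
}

#' Active-reaction mask under a hypothesis and a gene deletion set
#'
#' Reaction `j` is active iff its own GPR rule evaluates true under the
#' deletion set, or some hypothesised fact `function(g, j)` supplies a
#' non-deleted gene `g` for it. Hypotheses thereby extend the background
#' knowledge of masked (`unknown`-rule) reactions; several facts for one
#' reaction act as isoenzymes (OR).
#'
#' @param net a [metabolic_network()].
#' @param hypothesis a [hypothesis()] (possibly empty) or `NULL`.
#' @param deleted character vector of deleted gene ids.
#' @return named integer 0/1 vector over reactions.
#' @export
reaction_mask <- function(net, hypothesis = NULL, deleted = character()) {
  stopifnot(inherits(net, "metabolic_network"))
  deleted <- as.character(deleted)
  unknown_gene <- setdiff(deleted, net$genes)
  if (length(unknown_gene) > 0L) {
    stop("unknown gene id(s) in deletion set: ",
         paste(unknown_gene, collapse = ", "), call. = FALSE)
  }
  mask <- vapply(net$reactions, function(r) evaluate_gpr(r$rule, deleted),
                 logical(1L))
  names(mask) <- reaction_ids(net)
  if (!is.null(hypothesis) && hypothesis_size(hypothesis) > 0L) {
    facts <- hypothesis$facts
    bad_rxn <- setdiff(unique(facts$reaction), names(mask))
    if (length(bad_rxn) > 0L) {
      stop("hypothesis names unknown reaction(s): ",
           paste(bad_rxn, collapse = ", "), call. = FALSE)
    }
    bad_gene <- setdiff(unique(facts$gene), net$genes)
    if (length(bad_gene) > 0L) {
      stop("hypothesis names unknown gene(s): ",
           paste(bad_gene, collapse = ", "), call. = FALSE)
    }
    live <- facts[!(facts$gene %in% deleted), , drop = FALSE]
    mask[unique(live$reaction)] <- TRUE
  }
  storage.mode(mask) <- "integer"
  mask
}
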