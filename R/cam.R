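# Codon aversion motifs (CAMs): the set of sense codons a gene never uses
# in a strain, compared as canonical sorted sets, and the greedy decision
# map that identifies strains from their motifs.

#' Extract the codon aversion motif of one gene/strain
#'
#' The motif is the lexicographically sorted set of reportable sense codons
#' (single-codon families excluded) with zero usage — equivalently the
#' codons with RSCU 0.
#'
#' @param counts A `codon_counts`.
#' @return Sorted character vector of absent codons (possibly empty).
#' @export
extract_cam <- function(counts) {
  if (!isTRUE(counts$eligible)) {
    warning("gene '", counts$gene_id, "', strain '", counts$strain_id,
            "' is ineligible for motif extraction", call. = FALSE)
    return(character(0))
  }
  sort(REPORTABLE_CODONS[counts$counts[REPORTABLE_CODONS] == 0L])
}

# Canonical string form used for motif equality.
motif_string <- function(motif) paste(sort(motif), collapse = ",")

#' Tabulate motifs for a panel of codon counts
#'
#' @param counts_list List of `codon_counts` (one per gene x strain).
#' @return `data.frame`: `gene_id`, `strain_id`, `motif` (comma-joined
#'   canonical form), `n_codons_absent`. Ineligible records are skipped.
#' @export
cam_table <- function(counts_list) {
  keep <- vapply(counts_list, function(cc) isTRUE(cc$eligible), TRUE)
  counts_list <- counts_list[keep]
  motifs <- lapply(counts_list, extract_cam)
  data.frame(
    gene_id = vapply(counts_list, `[[`, "", "gene_id"),
    strain_id = vapply(counts_list, `[[`, "", "strain_id"),
    motif = vapply(motifs, motif_string, ""),
    n_codons_absent = lengths(motifs),
    stringsAsFactors = FALSE, row.names = NULL)
}

# gene -> named character vector strain -> motif string; genes missing any
# requested strain are dropped (with a warning from callers that care).
motif_matrix <- function(cams, strain_ids) {
  genes <- unique(cams$gene_id)
  out <- list()
  incomplete <- character(0)
  for (g in genes) {
    sub <- cams[cams$gene_id == g, , drop = FALSE]
    m <- stats::setNames(sub$motif, sub$strain_id)
    if (!all(strain_ids %in% names(m))) {
      incomplete <- c(incomplete, g)
      next
    }
    out[[g]] <- m[strain_ids]
  }
  attr(out, "incomplete") <- incomplete
  out
}

#' Genes whose motifs separate the two lineages
#'
#' A gene is group-diagnostic when no motif value occurs in both lineages:
#' the lineages' motif-value sets are disjoint, so any strain of either
#' lineage is classified without error. Genes lacking a motif for some
#' strain are excluded with a warning.
#'
#' @param cams Motif table from [cam_table()].
#' @param strains A [strain_table()].
#' @return Character vector of diagnostic gene ids.
#' @export
group_diagnostic_genes <- function(cams, strains) {
  mm <- motif_matrix(cams, strains$strain_id)
  if (length(attr(mm, "incomplete")) > 0L) {
    warning("excluding gene(s) with missing motifs: ",
            paste(attr(mm, "incomplete"), collapse = ", "), call. = FALSE)
  }
  ls <- lineages(strains)
  ga <- lineage_strains(strains, ls[1])
  gb <- lineage_strains(strains, ls[2])
  genes <- names(mm)
  diag <- vapply(genes, function(g) {
    length(intersect(mm[[g]][ga], mm[[g]][gb])) == 0L
  }, TRUE)
  sort(genes[diag])
}

#' Strain-specific motif resolution per gene
#'
#' For each gene, which strains carry a motif unique across the panel
#' ("perfect" genes make every strain unique), together with the number of
#' motif-equality blocks as the gene's partition refinement level.
#'
#' @param cams Motif table from [cam_table()].
#' @param strains A [strain_table()].
#' @return List: `by_gene` (`gene_id`, `n_blocks`, `perfect`,
#'   `unique_strains`), `by_strain` (strain -> genes where that strain's
#'   motif is unique).
#' @export
strain_specific_cams <- function(cams, strains) {
  mm <- motif_matrix(cams, strains$strain_id)
  genes <- names(mm)
  rows <- lapply(genes, function(g) {
    m <- mm[[g]]
    tab <- table(m)
    uniq <- names(m)[m %in% names(tab)[tab == 1L]]
    data.frame(gene_id = g, n_blocks = length(tab),
               perfect = length(tab) == length(m),
               unique_strains = join_strains(uniq), stringsAsFactors = FALSE)
  })
  by_gene <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  by_gene <- by_gene[order(by_gene$gene_id), , drop = FALSE]
  by_strain <- lapply(stats::setNames(strains$strain_id, strains$strain_id),
                      function(s) {
    sort(by_gene$gene_id[vapply(split_strains(by_gene$unique_strains),
                                function(u) s %in% u, TRUE)])
  })
  list(by_gene = by_gene, by_strain = by_strain)
}

new_map_node <- function(strains, gene = NA_character_,
                         alternatives = character(0),
                         children = NULL, separable = TRUE) {
  list(strains = strains, gene = gene, alternatives = alternatives,
       children = children, separable = separable)
}

# Choose the splitting gene at one node: most motif-equality blocks, then
# fewest total motif codons over the node's strains, then lexicographic
# gene id; genes tied after the first two criteria are kept as recorded
# alternative pathways.
choose_gene <- function(mm, node_strains, candidates) {
  stats_df <- data.frame(gene = candidates, stringsAsFactors = FALSE)
  stats_df$blocks <- vapply(candidates, function(g)
    length(unique(mm[[g]][node_strains])), 0L)
  stats_df$codons <- vapply(candidates, function(g) {
    m <- mm[[g]][node_strains]
    sum(lengths(strsplit(m[m != ""], ",", fixed = TRUE)))
  }, 0)
  best_blocks <- max(stats_df$blocks)
  if (best_blocks <= 1L) return(NULL)
  tied <- stats_df[stats_df$blocks == best_blocks, , drop = FALSE]
  tied <- tied[tied$codons == min(tied$codons), , drop = FALSE]
  tied <- tied[order(tied$gene), , drop = FALSE]
  list(gene = tied$gene[1], alternatives = tied$gene[-1])
}

#' Build the strain-identification decision map
#'
#' Greedy tree construction: each internal node picks the gene whose
#' motif-equality classes split the node's strains into the most blocks
#' (ties: fewest total motif codons, then lexicographic gene id; remaining
#' ties are recorded as alternative pathways). With `lineage_first`, the
#' root must use a group-diagnostic gene when one exists. Strains that no
#' remaining gene separates end in a flagged non-separable leaf.
#'
#' @param cams Motif table from [cam_table()].
#' @param strains A [strain_table()].
#' @param lineage_first Prefer a group-diagnostic gene at the root.
#' @return Object of class `identification_map`.
#' @export
build_identification_map <- function(cams, strains, lineage_first = TRUE) {
  mm <- motif_matrix(cams, strains$strain_id)
  if (length(mm) == 0L) stop("construction error: no gene has motifs for all strains")
  diag_genes <- tryCatch(
    suppressWarnings(group_diagnostic_genes(cams, strains)),
    error = function(e) character(0))

  grow <- function(node_strains, used, at_root) {
    if (length(node_strains) == 1L) {
      return(new_map_node(node_strains))
    }
    candidates <- setdiff(names(mm), used)
    if (at_root && lineage_first && length(intersect(candidates, diag_genes)) > 0L) {
      pick <- choose_gene(mm, node_strains, intersect(candidates, diag_genes))
      if (is.null(pick)) pick <- choose_gene(mm, node_strains, candidates)
    } else if (length(candidates) > 0L) {
      pick <- choose_gene(mm, node_strains, candidates)
    } else {
      pick <- NULL
    }
    if (is.null(pick)) {
      return(new_map_node(node_strains, separable = FALSE))
    }
    m <- mm[[pick$gene]][node_strains]
    blocks <- split(node_strains, m)
    children <- lapply(blocks, function(b)
      grow(b, c(used, pick$gene), FALSE))
    new_map_node(node_strains, pick$gene, pick$alternatives, children)
  }

  root <- grow(strains$strain_id, character(0), TRUE)
  structure(list(root = root, strains = strains$strain_id,
                 genes = names(mm), lineage_first = lineage_first),
            class = "identification_map")
}

map_leaves <- function(node) {
  if (is.null(node$children)) return(list(node))
  do.call(c, lapply(node$children, map_leaves))
}

#' Leaf partition of an identification map
#' @param map An `identification_map`.
#' @return List of character vectors (the strain blocks at the leaves).
#' @export
map_partition <- function(map) {
  lapply(map_leaves(map$root), `[[`, "strains")
}

#' Non-separable leaves of an identification map
#' @param map An `identification_map`.
#' @return List of strain sets (length > 1) that no gene could split.
#' @export
map_unresolved <- function(map) {
  lv <- map_leaves(map$root)
  lapply(Filter(function(n) !n$separable, lv), `[[`, "strains")
}

#' @export
print.identification_map <- function(x, ...) {
  part <- map_partition(x)
  cat("<identification_map>", length(x$strains), "strains,",
      length(part), "leaves,", length(map_unresolved(x)),
      "non-separable\n")
  invisible(x)
}

#' Identify a strain from its per-gene motifs
#'
#' Descends the map along matching motif branches. A motif that matches no
#' branch (a novel motif) stops the descent with the current node's strain
#' set as the ambiguity set — never a silent wrong answer; a query missing
#' a needed gene yields a partial-descent candidate set.
#'
#' @param query Named character vector or list: gene id -> motif (either a
#'   codon vector or a canonical comma-joined string).
#' @param map An `identification_map`.
#' @return List: `strain_id` (or `NA`), `candidates`, `status` in
#'   `"identified"`, `"novel_motif"`, `"missing_gene"`,
#'   `"non_separable"`.
#' @export
identify_strain <- function(query, map) {
  norm <- function(m) {
    if (length(m) == 0L || all(is.na(m))) return(NA_character_)
    if (length(m) == 1L) m <- strsplit(as.character(m), ",", fixed = TRUE)[[1]]
    motif_string(m)
  }
  q <- vapply(query, norm, "")
  names(q) <- names(query)
  node <- map$root
  while (!is.null(node$children)) {
    g <- node$gene
    if (!(g %in% names(q)) || is.na(q[[g]])) {
      return(list(strain_id = NA_character_, candidates = node$strains,
                  status = "missing_gene"))
    }
    hit <- match(q[[g]], names(node$children))
    branch <- if (is.na(hit)) NULL else node$children[[hit]]
    if (is.null(branch)) {
      return(list(strain_id = NA_character_, candidates = node$strains,
                  status = "novel_motif"))
    }
    node <- branch
  }
  if (length(node$strains) == 1L && node$separable) {
    list(strain_id = node$strains, candidates = node$strains,
         status = "identified")
  } else {
    list(strain_id = NA_character_, candidates = node$strains,
         status = "non_separable")
  }
}

map_node_to_list <- function(node) {
  out <- list(strains = node$strains)
  if (!is.null(node$children)) {
    out$gene <- node$gene
    if (length(node$alternatives) > 0L) out$alternatives <- node$alternatives
    out$children <- lapply(node$children, map_node_to_list)
  } else if (!node$separable) {
    out$non_separable <- TRUE
  }
  out
}

#' Export an identification map as JSON
#' @param map An `identification_map`.
#' @param path Output path.
#' @export
write_map_json <- function(map, path) {
  jsonlite::write_json(map_node_to_list(map$root), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Export an identification map as Graphviz DOT
#' @param map An `identification_map`.
#' @param path Output path.
#' @export
write_map_dot <- function(map, path) {
  lines <- c("digraph identification_map {", "  node [shape=box];")
  counter <- local({i <- 0L; function() {i <<- i + 1L; paste0("n", i)}})
  emit <- function(node) {
    id <- counter()
    label <- if (is.null(node$children)) {
      paste0(join_strains(node$strains),
             if (!node$separable) "\\n[non-separable]" else "")
    } else {
      paste0(node$gene,
             if (length(node$alternatives) > 0L)
               paste0("\\nalt: ", join_strains(node$alternatives)) else "")
    }
    lines <<- c(lines, sprintf('  %s [label="%s"];', id, label))
    if (!is.null(node$children)) {
      for (k in seq_along(node$children)) {
        cid <- emit(node$children[[k]])
        m <- names(node$children)[k]
        lab <- if (m == "") "(none)" else m
        lines <<- c(lines, sprintf('  %s -> %s [label="%s"];', id, cid, lab))
      }
    }
    id
  }
  emit(map$root)
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
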