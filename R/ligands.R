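#' Phenomenological nucleotide models
#'
#' Ligands are extra network nodes that move like residue beads (same
#' friction scaling). ADP is a single node placed at a reference position
#' and connected by ordinary elastic links (stiffness `kappa`) to every
#' protein bead within the network cutoff, with natural lengths equal to
#' the insertion distances -- so adding ADP leaves the equilibrium
#' conformation of the protein untouched. ATP is modelled as an ADP +
#' phosphate (Pi) dimer: the Pi node is placed at the unweighted centroid
#' of three designated "sensitive" beads and the ADP node, and linked to
#' those four partners with natural lengths shortened to
#' `prestrain * insertion distance` (default 0.20, i.e. 80% shorter than
#' the insertion distances). The Pi links are therefore born stretched and
#' pull the nucleotide-binding region together.
#'
#' @param net an `elastic_network`.
#' @param position numeric length-3 reference position of the ADP node
#'   (for actin, the ribose-adenine bridging carbon of the bound
#'   nucleotide; see [nucleotide_center()]).
#' @return The augmented network.
#' @name ligands
NULL

ligand_node_index <- function(net, name) {
  row <- which(net$ligands$name == name)
  if (length(row) == 0L) return(NA_integer_)
  nrow(net$structure) + row
}

#' @rdname ligands
#' @export
add_adp <- function(net, position) {
  position <- as.numeric(position)
  stopifnot(length(position) == 3L, all(is.finite(position)))
  if (!is.na(ligand_node_index(net, "ADP"))) {
    stop("network already carries an ADP node", call. = FALSE)
  }
  xyz <- coords_matrix(net$structure)
  d <- sqrt(rowSums(sweep(xyz, 2L, position)^2))
  nb <- which(d < net$cutoff)
  if (length(nb) == 0L) {
    stop("no protein bead within the cutoff of the ADP position", call. = FALSE)
  }
  net$ligands <- dplyr::bind_rows(
    net$ligands,
    tibble::tibble(name = "ADP", x = position[1], y = position[2],
                   z = position[3]))
  node <- ligand_node_index(net, "ADP")
  new_links <- tibble::tibble(i = as.integer(nb), j = as.integer(node),
                              r0 = d[nb], res_i = net$structure$residue_id[nb],
                              res_j = NA_integer_)
  net$links <- dplyr::bind_rows(net$links, new_links)
  net$ligand_links <- dplyr::bind_rows(net$ligand_links, new_links)
  net
}

#' @rdname ligands
#' @param sensitive three residue ids bridging the two domains to which the
#'   phosphate binds (actin defaults 16, 73, 159).
#' @param prestrain retained-length fraction of the Pi links (0.20 means
#'   the natural lengths are 80% shorter than the insertion distances;
#'   1.0 gives unstrained links).
#' @export
add_atp <- function(net, sensitive = c(16L, 73L, 159L), prestrain = 0.2) {
  stopifnot(length(sensitive) == 3L, prestrain > 0)
  adp <- ligand_node_index(net, "ADP")
  if (is.na(adp)) stop("add ADP before the phosphate (ATP = ADP + Pi dimer)",
                       call. = FALSE)
  if (!is.na(ligand_node_index(net, "Pi"))) {
    stop("network already carries a Pi node", call. = FALSE)
  }
  idx <- match(sensitive, net$structure$residue_id)
  if (anyNA(idx)) stop("sensitive residue id(s) not in the structure", call. = FALSE)
  coords <- network_coords(net)
  partners <- c(idx, adp)
  pos <- unname(colMeans(coords[partners, , drop = FALSE]))
  net$ligands <- dplyr::bind_rows(
    net$ligands,
    tibble::tibble(name = "Pi", x = pos[1], y = pos[2], z = pos[3]))
  node <- ligand_node_index(net, "Pi")
  d <- sqrt(rowSums(sweep(coords[partners, , drop = FALSE], 2L, pos)^2))
  new_links <- tibble::tibble(
    i = as.integer(partners), j = as.integer(node), r0 = prestrain * d,
    res_i = c(sensitive, NA_integer_), res_j = NA_integer_)
  net$links <- dplyr::bind_rows(net$links, new_links)
  net$ligand_links <- dplyr::bind_rows(net$ligand_links, new_links)
  net
}

#' @rdname ligands
#' @details `release_pi()` imitates hydrolysis-product release: the Pi node
#'   and every link attached to it are removed and nothing else changes, so
#'   `add_atp()` followed by `release_pi()` restores the ADP-only network.
#' @export
release_pi <- function(net) {
  node <- ligand_node_index(net, "Pi")
  if (is.na(node)) stop("no Pi node present", call. = FALSE)
  drop_links <- function(tab) {
    tab <- tab[tab$i != node & tab$j != node, , drop = FALSE]
    tab$i <- ifelse(tab$i > node, tab$i - 1L, tab$i)
    tab$j <- ifelse(tab$j > node, tab$j - 1L, tab$j)
    tab
  }
  net$links <- drop_links(net$links)
  net$ligand_links <- drop_links(net$ligand_links)
  net$ligands <- net$ligands[net$ligands$name != "Pi", , drop = FALSE]
  net
}

#' Reference position of a bound nucleotide's bridging carbon
#'
#' Reads the HETATM record of the named atom of a bound nucleotide from a
#' PDB file (the C1' carbon joins the ribose to the adenine and sits at the
#' center of the ADP moiety), for use as the ADP node position.
#'
#' @param path PDB file.
#' @param resid HETATM residue name (e.g. `"ADP"`).
#' @param elety atom name (default `"C1'"`).
#' @return Numeric length-3 position.
#' @export
nucleotide_center <- function(path, resid = "ADP", elety = "C1'") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  sel <- at$type == "HETATM" & at$resid == resid & at$elety %in%
    c(elety, gsub("'", "*", elety, fixed = TRUE))
  if (!any(sel)) stop("no HETATM ", resid, " atom ", elety, " in ", path,
                      call. = FALSE)
  as.numeric(at[which(sel)[1], c("x", "y", "z")])
}
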