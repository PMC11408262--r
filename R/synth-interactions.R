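# Synthetic multi-layer interaction universe.
#
# Two structures are planted and wired together so that every downstream
# network operation has known ground truth:
#
#  * a hub-centric "star": 3 hub miRNAs target protein-coding genes in all 7
#    non-empty regulator-signature combinations (plus pseudogenes and other
#    ncRNAs), and 3 hub proteins carry a miRNA cluster each and a set of
#    protein-protein partners;
#  * two seed-gene chains ("extrinsic" and "intrinsic") whose first-order
#    networks prune to minimum networks of 45 and 43 nodes sharing exactly
#    the 6 hub genes. Every chain node adjacent to a hub gene is drawn from
#    that hub gene's own interactor pool, so hub expansion counts are not
#    perturbed by the seed networks.
#
# Prunable decoy leaves are attached to seeds so that minimization has real
# work to do. A separate lncRNA interaction table links personality lncRNAs
# to new miRNAs/ncRNAs (network extension) and to existing members.

#' Generate typed interaction tables with a planted control hub
#'
#' @param cfg a [synth_config()] object.
#' @return An object of class `interaction_set`: a list with
#'   \describe{
#'     \item{edges}{tibble `(source, target, layer)`,
#'       layer in `ppi`, `tf_gene`, `mirna_gene`; no self loops, no
#'       duplicate edges.}
#'     \item{node_types}{tibble `(node, type, biotype)`.}
#'     \item{lnc_expansion}{lncRNA edges reaching genes outside the
#'       hub-expanded network (drives the network extension).}
#'     \item{lnc_links}{lncRNA edges landing on genes already inside it.}
#'     \item{truth}{planted structure: hub, seed sets, expected minimum
#'       network node sets, per-signature gene pools, lncRNA gene lists.}
#'   }
#' @examples
#' cfg <- synth_config(signature_counts = c(A = 20, B = 25, C = 15, AB = 6,
#'                                          AC = 4, BC = 5, ABC = 3),
#'                     ppi_only_pc = 12, mirna_cluster_sizes = c(4, 4, 4),
#'                     n_pseudogenes = 3, n_other_ncrna = 3)
#' it <- gen_interactions(cfg)
#' nrow(it$edges)
#' @export
gen_interactions <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  validate_synth_config(cfg)
  sig <- cfg$signature_counts
  for (s in c("A", "B", "C")) {
    if (sig[[s]] < 4)
      config_error("signature_counts",
                   sprintf("singleton pool '%s' needs >= 4 genes to wire the seed networks", s))
  }
  mirnas <- cfg$hub_mirnas
  proteins <- cfg$hub_proteins
  sig_defs <- list(A = 1L, B = 2L, C = 3L, AB = 1:2, AC = c(1L, 3L),
                   BC = 2:3, ABC = 1:3)

  with_seed(substream_seed(cfg$rng_seed, "interactions"), {
    ## ---- hub star -------------------------------------------------------
    n_pc <- sum(sig) + cfg$ppi_only_pc
    pc_ids <- make_ids("P", n_pc, width = 5)
    cuts <- cumsum(c(sig, ppi = cfg$ppi_only_pc))
    starts <- c(1L, head(cuts, -1) + 1L)
    pools <- purrr::map2(starts, cuts, function(a, b) pc_ids[a:b])
    names(pools) <- names(cuts)
    ppi_pools <- split(pools$ppi,
                       rep(proteins, length.out = length(pools$ppi)))
    cluster_ids <- make_ids("mirC", sum(cfg$mirna_cluster_sizes), width = 3)
    cluster_pools <- split(cluster_ids,
                           rep(proteins, times = cfg$mirna_cluster_sizes))
    pseudo_ids <- make_ids("PSG", cfg$n_pseudogenes, width = 3)
    ncrna_ids <- make_ids("NCR", cfg$n_other_ncrna, width = 3)

    star <- list()
    for (lbl in names(sig_defs)) {
      for (i in sig_defs[[lbl]]) {
        star[[length(star) + 1L]] <- tibble(
          source = mirnas[i], target = pools[[lbl]], layer = "mirna_gene")
      }
    }
    for (p in proteins) {
      star[[length(star) + 1L]] <- tibble(
        source = ppi_pools[[p]], target = p, layer = "ppi")
      star[[length(star) + 1L]] <- tibble(
        source = cluster_pools[[p]], target = p, layer = "mirna_gene")
    }
    # pseudogenes and other ncRNAs: single hub-miRNA targets, round-robin
    if (cfg$n_pseudogenes > 0)
      star[[length(star) + 1L]] <- tibble(
        source = rep(mirnas, length.out = cfg$n_pseudogenes),
        target = pseudo_ids, layer = "mirna_gene")
    if (cfg$n_other_ncrna > 0)
      star[[length(star) + 1L]] <- tibble(
        source = rep(mirnas, length.out = cfg$n_other_ncrna),
        target = ncrna_ids, layer = "mirna_gene")
    star <- bind_rows(star)

    ## ---- seed chains ----------------------------------------------------
    # reserve 4 interactors per hub gene: (adjacent seed, gap partner) for
    # each of the two chains; draws are disjoint so the chains share only
    # the hub itself
    hub_nodes <- c(mirnas, proteins)
    reserve <- vector("list", 6)
    names(reserve) <- hub_nodes
    for (i in 1:3) reserve[[mirnas[i]]] <- pools[[c("A", "B", "C")[i]]][1:4]
    for (p in proteins) reserve[[p]] <- ppi_pools[[p]][1:4]

    chainA <- build_seed_chain(n_seeds = 16L, double_gaps = 14L,
                               hub_nodes = hub_nodes, reserve = reserve,
                               slot = 1:2, tag = "A", n_decoys = cfg$n_decoys)
    chainB <- build_seed_chain(n_seeds = 15L, double_gaps = 14L,
                               hub_nodes = hub_nodes, reserve = reserve,
                               slot = 3:4, tag = "B", n_decoys = cfg$n_decoys)

    ## ---- node types -----------------------------------------------------
    node_types <- bind_rows(
      tibble(node = mirnas, type = "mirna", biotype = "mirna"),
      tibble(node = proteins, type = "protein", biotype = "protein_coding"),
      tibble(node = pc_ids, type = "protein", biotype = "protein_coding"),
      tibble(node = cluster_ids, type = "mirna", biotype = "mirna"),
      tibble(node = pseudo_ids, type = "other", biotype = "pseudogene"),
      tibble(node = ncrna_ids, type = "other", biotype = "other_ncrna"),
      chainA$fresh_types, chainB$fresh_types)

    type_of <- setNames(node_types$type, node_types$node)
    chain_edges <- bind_rows(chainA$edge_pairs, chainB$edge_pairs)
    chain_edges <- typed_edges(chain_edges$a, chain_edges$b, type_of)

    edges <- bind_rows(star, chain_edges) |>
      filter(.data$source != .data$target) |>
      distinct(.data$source, .data$target, .data$layer)

    ## ---- lncRNA tables --------------------------------------------------
    lncs <- make_ids("LNC", cfg$n_personality_lncrnas, width = 2)
    lnc_mirna_ids <- make_ids("mirL", cfg$n_lnc_mirnas, width = 3)
    lnc_ncrna_ids <- make_ids("NCL", cfg$n_lnc_ncrnas, width = 2)
    new_nodes <- c(lnc_mirna_ids, lnc_ncrna_ids)
    lnc_expansion <- tibble(
      source = rep(lncs, length.out = length(new_nodes)),
      target = new_nodes, layer = "lncrna_gene")
    # links into the existing hub-expanded network
    members <- c(proteins, cluster_ids, pc_ids)
    link_targets <- sample(members, cfg$n_lnc_link_edges, replace = FALSE)
    lnc_links <- tibble(
      source = rep(lncs, length.out = cfg$n_lnc_link_edges),
      target = link_targets, layer = "lncrna_gene")

    node_types <- bind_rows(
      node_types,
      tibble(node = lncs, type = "lncrna", biotype = "lncrna"),
      tibble(node = lnc_mirna_ids, type = "mirna", biotype = "mirna"),
      tibble(node = lnc_ncrna_ids, type = "other", biotype = "other_ncrna"))
  })

  truth <- list(
    hub = list(mirnas = mirnas, proteins = proteins),
    seed_sets = list(extrinsic = chainA$seeds, intrinsic = chainB$seeds),
    min_networks = list(extrinsic = chainA$chain_nodes,
                        intrinsic = chainB$chain_nodes),
    pools = c(pools[setdiff(names(pools), "ppi")],
              list(ppi = ppi_pools, clusters = cluster_pools,
                   pseudogenes = pseudo_ids, other_ncrnas = ncrna_ids)),
    tcmin_members = c(pc_ids, cluster_ids, pseudo_ids, ncrna_ids),
    lncrnas = lncs,
    lnc_new_genes = c(lnc_mirna_ids, lnc_ncrna_ids))

  structure(list(edges = edges, node_types = node_types,
                 lnc_expansion = lnc_expansion, lnc_links = lnc_links,
                 truth = truth),
            class = "interaction_set")
}

# A chain of seed genes with 1- or 2-connector gaps. Every connector lies on
# the unique seed-to-seed path, so greedy minimization keeps exactly the
# chain; decoy leaves hang off seeds and are pruned. The first six (double)
# gaps carry the hub genes, each paired with a partner from its own
# interactor pool; the hub-adjacent seed on the left of each such gap is
# drawn from the same pool.
build_seed_chain <- function(n_seeds, double_gaps, hub_nodes, reserve,
                             slot, tag, n_decoys) {
  n_gaps <- n_seeds - 1L
  stopifnot(double_gaps <= n_gaps, length(hub_nodes) <= double_gaps)
  seeds <- character(n_seeds)
  fresh_seed_ids <- make_ids(paste0("SD", tag), n_seeds, width = 2)
  for (j in seq_len(6L)) seeds[j] <- reserve[[hub_nodes[j]]][slot[1]]
  seeds[7:n_seeds] <- fresh_seed_ids[7:n_seeds]

  n_fresh_conn <- (double_gaps - 6L) * 2L + (n_gaps - double_gaps)
  conn_ids <- make_ids(paste0("CX", tag), n_fresh_conn, width = 2)
  conn_types <- rep(c("tf", "protein"), length.out = n_fresh_conn)

  seq_nodes <- character(0)
  ci <- 1L
  for (g in seq_len(n_gaps)) {
    seq_nodes <- c(seq_nodes, seeds[g])
    if (g <= 6L) {
      seq_nodes <- c(seq_nodes, hub_nodes[g], reserve[[hub_nodes[g]]][slot[2]])
    } else if (g <= double_gaps) {
      seq_nodes <- c(seq_nodes, conn_ids[ci], conn_ids[ci + 1L])
      ci <- ci + 2L
    } else {
      seq_nodes <- c(seq_nodes, conn_ids[ci])
      ci <- ci + 1L
    }
  }
  seq_nodes <- c(seq_nodes, seeds[n_seeds])
  edge_pairs <- tibble(a = head(seq_nodes, -1), b = seq_nodes[-1])

  decoy_ids <- make_ids(paste0("DL", tag), n_decoys, width = 2)
  decoy_seats <- sample(seeds, n_decoys, replace = TRUE)
  edge_pairs <- bind_rows(edge_pairs, tibble(a = decoy_seats, b = decoy_ids))

  used_conn <- conn_ids[seq_len(ci - 1L)]
  fresh_types <- bind_rows(
    tibble(node = fresh_seed_ids[7:n_seeds], type = "protein",
           biotype = "protein_coding"),
    tibble(node = used_conn, type = conn_types[seq_len(ci - 1L)],
           biotype = "protein_coding"),
    tibble(node = decoy_ids, type = "tf", biotype = "protein_coding"))

  list(seeds = seeds, chain_nodes = unique(seq_nodes),
       edge_pairs = edge_pairs, fresh_types = fresh_types,
       decoys = decoy_ids)
}

# Assign a layer from endpoint types and canonicalize edge direction:
# miRNA sources come first, then TF sources; plain protein pairs are
# alphabetical protein-protein edges.
typed_edges <- function(a, b, type_of) {
  ta <- unname(type_of[a])
  tb <- unname(type_of[b])
  layer <- ifelse(ta == "mirna" | tb == "mirna", "mirna_gene",
                  ifelse(ta == "tf" | tb == "tf", "tf_gene", "ppi"))
  swap <- (tb == "mirna" & ta != "mirna") |
    (layer == "tf_gene" & tb == "tf" & ta != "tf") |
    (layer == "ppi" & a > b)
  tibble(source = ifelse(swap, b, a),
         target = ifelse(swap, a, b),
         layer = layer)
}

#' @export
print.interaction_set <- function(x, ...) {
  cat(sprintf("<interaction_set> %d edges, %d nodes (+%d lncRNA-table edges)\n",
              nrow(x$edges), nrow(x$node_types),
              nrow(x$lnc_expansion) + nrow(x$lnc_links)))
  invisible(x)
}
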