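#' Default tissue volume targets for the synthetic worm (µm³)
#'
#' Chosen once to echo the composition of a young-adult hermaphrodite model:
#' total 1.4e6 µm³ with intestine > hypodermis > gonads (somatic + germline)
#' > body wall muscle > pharynx > neurons, the germline/rachis near 1/8 of
#' the total, and an extracellular cuticle shell.
#' @export
default_tissue_volumes <- c(
  "intestine" = 340000, "hypodermis" = 300000, "body wall muscle" = 250000,
  "germline" = 175000, "cuticle" = 120000, "somatic gonad" = 110000,
  "pharynx" = 65000, "neurons" = 40000)

#' Default cell counts per tissue for the synthetic worm
#' @export
default_cell_counts <- c(
  "intestine" = 9L, "hypodermis" = 6L, "body wall muscle" = 12L,
  "pharynx" = 8L, "neurons" = 20L, "somatic gonad" = 5L)

#' Generate a synthetic virtual worm
#'
#' Writes a complete, self-consistent test world to `dir`:
#' \itemize{
#'   \item a mesh collection `<dir>/meshes/<tissue>/<cell>.obj` with, by
#'     construction, one 139-nucleus hyp7-like syncytium (60% of hypodermis
#'     volume), nine 32C polyploid intestine-like cells, a nested-box cuticle
#'     shell (nuclei 0), a capsule germline/rachis pseudo-record
#'     (somatic = FALSE) and the 100-model-unit calibration cube in a
#'     `reference` collection;
#'   \item `<dir>/anatomy.csv` with matching nuclei/ploidy records;
#'   \item `<dir>/manifest.json` holding every ground-truth volume (computed
#'     with the winding-independent [convex_volume_oracle()], never with
#'     [signed_volume()]) plus the expected tissue totals, volume/nuclei
#'     fractions with and without the germline, per-genome volumes and the
#'     constructed tissue ranking.
#' }
#' Per-cell sizes within a tissue are log-normal draws renormalised so each
#' tissue hits its volume target; shapes cycle through box, icosphere,
#' convex hull and capsule families. Fully deterministic given `seed`
#' (single global seed, no hidden entropy).
#'
#' @param dir output directory (created if needed).
#' @param n_cells_per_tissue named integer vector of cells per tissue
#'   (default [default_cell_counts]); must have >= 1 tissue.
#' @param tissue_volumes_um3 named volume targets incl. `cuticle` and
#'   `germline` (default [default_tissue_volumes]).
#' @param size_sdlog log-normal sdlog for within-tissue size variation.
#' @param seed integer RNG seed.
#' @param cube_edge calibration cube edge in model units (its known physical
#'   volume is fixed at 1e6 µm³, so model units are µm when `cube_edge` is
#'   100).
#' @return The manifest, invisibly, as a list (also written as JSON).
#' @export
generate_worm <- function(dir,
                          n_cells_per_tissue = default_cell_counts,
                          tissue_volumes_um3 = default_tissue_volumes,
                          size_sdlog = 0.6,
                          seed = 1L,
                          cube_edge = 100) {
  if (!length(n_cells_per_tissue) || is.null(names(n_cells_per_tissue)))
    stop("n_cells_per_tissue must be a named vector with at least one tissue")
  if (any(n_cells_per_tissue < 1L)) stop("every tissue needs >= 1 cell")
  if (size_sdlog < 0) stop("size_sdlog must be >= 0")
  miss <- setdiff(names(n_cells_per_tissue), names(tissue_volumes_um3))
  if (length(miss))
    stop("no volume target for tissue(s): ", paste(miss, collapse = ", "))
  set.seed(as.integer(seed))
  mesh_root <- file.path(dir, "meshes")
  known_cube_volume <- 1e6
  factor <- known_cube_volume / cube_edge^3   # µm³ per model-unit³

  shape_cycle <- c("box", "icosphere", "hull", "capsule")
  prefix <- c("intestine" = "int", "hypodermis" = "hyp",
              "body wall muscle" = "mus", "pharynx" = "pha",
              "neurons" = "neu", "somatic gonad" = "gon")

  cells <- list()
  offset_i <- 0L
  add_cell <- function(mesh, tissue, name, vol_um3, nuclei, ploidy, somatic) {
    d <- file.path(mesh_root, tissue)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_mesh(mesh, file.path(d, paste0(name, ".obj")))
    cells[[length(cells) + 1L]] <<- list(
      name = name, tissue = tissue, shape = mesh$shape %||% "box",
      volume_um3 = vol_um3, nuclei = as.integer(nuclei),
      ploidy_c = as.double(ploidy), somatic = somatic)
  }

  for (tissue in names(n_cells_per_tissue)) {
    n <- n_cells_per_tissue[[tissue]]
    target <- tissue_volumes_um3[[tissue]]
    pf <- if (tissue %in% names(prefix)) prefix[[tissue]] else
      gsub("[^a-z]", "", substr(tissue, 1L, 3L))
    # hyp7-like giant syncytium: fixed 60% of the hypodermis target
    special <- tissue == "hypodermis" && n >= 2L
    nm <- sprintf("%s%02d", pf, seq_len(n))
    if (special) nm[1L] <- "hyp7"
    w <- stats::rlnorm(n, meanlog = 0, sdlog = size_sdlog)
    if (special) {
      vols <- c(0.6 * target, 0.4 * target * w[-1L] / sum(w[-1L]))
    } else {
      vols <- target * w / sum(w)
    }
    for (i in seq_len(n)) {
      offset_i <- offset_i + 1L
      center <- c(300 * offset_i, 0, 0)
      shape <- shape_cycle[(offset_i - 1L) %% 4L + 1L]
      target_model <- vols[i] / factor
      mesh <- switch(shape,
        box = make_box(rep(target_model^(1 / 3), 3L) * c(1.25, 1, 0.8),
                       center = center, name = nm[i]),
        icosphere = {
          m0 <- make_icosphere(1, subdivisions = 2L, name = nm[i])
          s <- (target_model / convex_volume_oracle(m0))^(1 / 3)
          bake_transform(m0, affine_transform(diag(3) * s, center))
        },
        hull = {
          m0 <- make_hull(matrix(stats::rnorm(3L * 14L), ncol = 3L), name = nm[i])
          s <- (target_model / convex_volume_oracle(m0))^(1 / 3)
          bake_transform(m0, affine_transform(diag(3) * s, center))
        },
        capsule = {
          m0 <- make_capsule(1, 2.5, name = nm[i])
          s <- (target_model / convex_volume_oracle(m0))^(1 / 3)
          bake_transform(m0, affine_transform(diag(3) * s, center))
        })
      mesh$shape <- shape
      nuclei <- 1L; ploidy <- 2
      if (tissue == "intestine") ploidy <- 32
      if (special && i == 1L) nuclei <- 139L
      add_cell(mesh, tissue, nm[i], convex_volume_oracle(mesh),
               nuclei, ploidy, somatic = TRUE)
    }
  }

  # germline/rachis pseudo-record: one capsule, non-somatic
  if ("germline" %in% names(tissue_volumes_um3)) {
    target_model <- tissue_volumes_um3[["germline"]] / factor
    m0 <- make_capsule(1, 6, name = "germline")
    s <- (target_model / convex_volume_oracle(m0))^(1 / 3)
    mesh <- bake_transform(m0, affine_transform(diag(3) * s, c(0, 500, 0)))
    mesh$shape <- "capsule"
    add_cell(mesh, "germline", "germline", convex_volume_oracle(mesh),
             1300L, 2, somatic = FALSE)
  }

  # cuticle: nested-box shell (outer box + inward-oriented inner box)
  if ("cuticle" %in% names(tissue_volumes_um3)) {
    target_model <- tissue_volumes_um3[["cuticle"]] / factor
    outer_edges <- c(6.25, 1, 0.64) * (2 * target_model)^(1 / 3)
    inner_scale <- (1 - target_model / prod(outer_edges))^(1 / 3)
    outer <- make_box(outer_edges, center = c(0, -500, 0), name = "cuticle")
    inner <- flip_faces(make_box(outer_edges * inner_scale,
                                 center = c(0, -500, 0), name = "inner"))
    shell <- triangle_mesh(rbind(outer$vertices, inner$vertices),
                           rbind(outer$faces, inner$faces + 8L),
                           name = "cuticle")
    shell$shape <- "shell"
    vol <- convex_volume_oracle(outer) - convex_volume_oracle(inner)
    add_cell(shell, "cuticle", "cuticle", vol, 0L, 2, somatic = TRUE)
  }

  # calibration cube
  ref_dir <- file.path(mesh_root, "reference")
  dir.create(ref_dir, recursive = TRUE, showWarnings = FALSE)
  write_mesh(make_box(rep(cube_edge, 3L), name = "100um_cube"),
             file.path(ref_dir, "100um_cube.obj"))

  cell_df <- do.call(rbind, lapply(cells, function(cl)
    data.frame(name = cl$name, tissue = cl$tissue, shape = cl$shape,
               volume_um3 = cl$volume_um3, nuclei = cl$nuclei,
               ploidy_c = cl$ploidy_c, somatic = cl$somatic,
               stringsAsFactors = FALSE)))

  # anatomy table
  anat <- data.frame(cell = cell_df$name, tissue = cell_df$tissue,
                     somatic = cell_df$somatic, nuclei = cell_df$nuclei,
                     ploidy_c = cell_df$ploidy_c, stringsAsFactors = FALSE)
  utils::write.csv(anat, file.path(dir, "anatomy.csv"), row.names = FALSE,
                   quote = FALSE)

  manifest <- list(
    seed = as.integer(seed),
    calibration = list(name = "100um_cube", collection = "reference",
                       edge_model_units = cube_edge,
                       known_volume_um3 = known_cube_volume,
                       volume_factor = factor),
    cells = cell_df,
    expected = .manifest_expected(cell_df)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Expected aggregates computed with plain arithmetic (deliberately not via
# summarize_tissues, so pipeline recovery tests compare two routes).
.manifest_expected <- function(cell_df) {
  totals <- tapply(cell_df$volume_um3, cell_df$tissue, sum)
  ge <- cell_df$nuclei * cell_df$ploidy_c / 2

  frac_over <- function(df, val) {
    t <- tapply(val, df$tissue, sum)
    as.list(t / sum(t))
  }
  incl <- cell_df[cell_df$tissue != "cuticle", ]
  excl <- incl[incl$somatic, ]

  vpg <- ge > 0
  per_genome <- stats::setNames(as.list(cell_df$volume_um3[vpg] / ge[vpg]),
                                cell_df$name[vpg])

  # ranking: cuticle excluded, gonads merged, germline included
  rank_tab <- tapply(incl$volume_um3, incl$tissue, sum)
  gon <- sum(rank_tab[names(rank_tab) %in% c("somatic gonad", "germline")])
  rank_tab <- rank_tab[!names(rank_tab) %in% c("somatic gonad", "germline")]
  if (gon > 0) rank_tab <- c(rank_tab, gonads = gon)
  ranking <- names(sort(rank_tab, decreasing = TRUE))

  list(
    tissue_totals = as.list(totals),
    total_volume_um3 = sum(cell_df$volume_um3),
    volume_fractions_incl_germline = frac_over(incl, incl$volume_um3),
    volume_fractions_excl_germline = frac_over(excl, excl$volume_um3),
    nuclei_fractions_incl_germline = frac_over(incl, incl$nuclei),
    nuclei_fractions_excl_germline = frac_over(excl, excl$nuclei),
    volume_per_genome = per_genome,
    ranking = ranking
  )
}

#' Read a worm manifest written by [generate_worm()]
#'
#' @param path the manifest JSON file (or the worm directory containing it).
#' @return The manifest list, with `cells` as a data.frame.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.json")
  jsonlite::read_json(path, simplifyVector = TRUE)
}
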