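# Fixtures are built in code at test time; no binary files ship with the
# package.

unit_cube <- function() make_box(c(1, 1, 1), name = "cube")

# the canonical unit tetrahedron: (0,0,0),(1,0,0),(0,1,0),(0,0,1), outward
unit_tetra <- function() {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 3, 2),   # z = 0, normal -z
             c(1, 2, 4),   # y = 0
             c(1, 4, 3),   # x = 0
             c(2, 3, 4))   # slanted, outward
  triangle_mesh(v, f, name = "tetra")
}

random_hull_mesh <- function(n_points, scale = 1) {
  make_hull(matrix(stats::rnorm(3L * n_points, sd = scale), ncol = 3L))
}

# Independent convex-hull-volume oracle: scipy.spatial.ConvexHull via the
# pre-installed python. Takes a list of point matrices, returns hull volumes.
scipy_hull_volumes <- function(point_sets) {
  inp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lapply(point_sets, unname), inp, digits = NA)
  script <- paste(
    "import json, sys",
    "from scipy.spatial import ConvexHull",
    "sets = json.load(open(sys.argv[1]))",
    "print(json.dumps([ConvexHull(s).volume for s in sets]))",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(script), shQuote(inp)), stdout = TRUE)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}

# tiny anatomy table built in code
toy_anatomy <- function() {
  data.frame(
    cell = c("a1", "a2", "b1", "b2", "germ", "cut"),
    tissue = c("intestine", "intestine", "neurons", "neurons",
               "germline", "cuticle"),
    somatic = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    nuclei = c(1L, 1L, 1L, 1L, 10L, 0L),
    ploidy_c = c(32, 32, 2, 2, 2, 2),
    stringsAsFactors = FALSE)
}

toy_measurements <- function(vols, cells, tissues) {
  data.frame(cell = cells, tissue = tissues, raw_volume = vols,
             calibrated_volume_um3 = vols, watertight = TRUE,
             orientation_consistent = TRUE, excluded = FALSE,
             stringsAsFactors = FALSE)
}

# one shared small synthetic worm per test run (generation is cheap but not
# free; several files reuse it read-only)
shared_worm_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir)) {
      dir <<- file.path(tempdir(), "wormvolumes-shared-worm")
      if (!dir.exists(dir)) generate_worm(dir, seed = 42L)
    }
    dir
  }
})
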