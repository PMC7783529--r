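Package: wormvolumes
Title: Cell and Tissue Volumes from Triangle-Mesh Anatomy Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes calibrated volumes of individual cell meshes from 3D
    anatomy models such as the Virtual Worm (a community Blender model of an
    adult Caenorhabditis elegans hermaphrodite) and aggregates them into tissue
    composition statistics. Reads and writes Wavefront OBJ, PLY and STL triangle
    meshes, validates watertightness and orientation, measures volumes with the
    divergence-theorem signed-tetrahedron sum, calibrates model units to
    cubic micrometres against a reference cube, joins volumes to an anatomy
    table encoding syncytial nuclei counts and ploidy (C-values), and reports
    tissue volume fractions, nuclei and diploid-genome shares, volumes per
    diploid genome, size distributions and tissue rankings. Includes a
    synthetic "virtual worm" generator with analytically known volumes for
    end-to-end testing without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
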