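Package: pflyolo
Title: Lightweight Grouped-Convolution Detection Networks for Sheep Face
    Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, profiles and evaluates PFL-YOLO, a lightweight variant of
    the YOLOv8n one-stage detector for individual sheep identification from
    face images. Implements the four lightweight blocks (EHConv grouped
    convolutions with efficient channel attention, the Res2Net-style RC2f
    fusion block, the grouped ESPPF pyramid-pooling block and the PFDetect
    shared detection head), assembles the 23-layer baseline and every ablation
    variant from declarative configurations, and counts parameters and FLOPs
    per layer against published budgets. Also provides the dataset-curation
    toolkit (SSIM near-duplicate filtering, YOLO-txt label validation,
    single-draw augmentation, split-then-augment partitioning), a synthetic
    face-dataset generator for end-to-end testing, detection metrics
    (precision, recall, F1, mAP@50, mAP@50:95), Grad-CAM heatmaps and heatmap
    area-of-interest measurement. The forward/backward network engine is
    implemented in base R.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
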