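{
  "manifest": "analysis",
  "note": "Minimal reporting parameters for uCT image segmentation, thresholding, analysis and other study descriptors.",
  "fields": [
    {"field": "density_measures", "row": "Bone density: whether BMD and/or TMD was examined", "type": "subset", "values": ["BMD", "TMD"], "modality": "both"},
    {"field": "bmd_roi_description", "row": "Bone density: description of the volume of interest used for BMD calculation", "type": "text", "modality": "both", "required_if": {"field": "density_measures", "contains": "BMD"}},
    {"field": "morphometry_mode", "row": "Morphometry: landmark-based and/or segmentation-based", "type": "subset", "values": ["landmark", "segmentation"], "modality": "both"},
    {"field": "landmark_details", "row": "Morphometry (landmark-based): how landmarking was performed", "type": "text", "modality": "both", "required_if": {"field": "morphometry_mode", "contains": "landmark"}},
    {"field": "segmentation_details", "row": "Morphometry (segmentation-based): methods used for quantification of measures", "type": "text", "modality": "both", "required_if": {"field": "morphometry_mode", "contains": "segmentation"}},
    {"field": "software_versions", "row": "Morphometry: functions and software (name and version) used for calculation", "type": "text", "modality": "both"},
    {"field": "roi_method", "row": "Segmentation: ROI by manual contours, geometric shape, or automatic generation", "type": "enum", "values": ["contours", "geometric", "automatic"], "modality": "both"},
    {"field": "roi_description", "row": "Segmentation: ROI specification details including landmarks employed", "type": "text", "modality": "both"},
    {"field": "threshold", "row": "Thresholding: global threshold (mg HA/cm3) or algorithm used for automatic calculation", "type": "threshold", "modality": "both"},
    {"field": "age", "row": "Age and standard length: age of the animals", "type": "text", "modality": "both"},
    {"field": "standard_length_mm", "row": "Age and standard length: standard length (mm SL)", "type": "number", "modality": "both"},
    {"field": "strain", "row": "Strain and sex: background strain", "type": "text", "modality": "both", "lenient": true},
    {"field": "sex", "row": "Strain and sex: male, female, or mixed-sex groups", "type": "enum", "values": ["male", "female", "mixed"], "modality": "both", "lenient": true},
    {"field": "controls", "row": "Experimental controls: controls used for experimental groups", "type": "text", "modality": "both", "lenient": true},
    {"field": "normalization", "row": "Normalization: method and justification", "type": "text", "modality": "both"},
    {"field": "image_presentation", "row": "Images: type of image, how generated, orientation convention (anterior left, dorsal up)", "type": "text", "modality": "both"}
  ]
}
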