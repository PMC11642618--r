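{
  "manifest": "acquisition",
  "note": "Minimal reporting parameters for 2D X-ray and 3D uCT image acquisition. 'modality' selects which conditional rows apply.",
  "fields": [
    {"field": "modality", "row": "Modality (xray2d or uct3d)", "type": "enum", "values": ["xray2d", "uct3d"], "modality": "both"},
    {"field": "sample_preparation", "row": "Sample preparation: method used (freshly euthanized, frozen, or fixed)", "type": "text", "modality": "both"},
    {"field": "in_vivo", "row": "Sample mounting and positioning: imaged in vivo or ex vivo", "type": "boolean", "modality": "both"},
    {"field": "whole_animal", "row": "Sample mounting and positioning: whole animals or dissected tissues", "type": "boolean", "modality": "both"},
    {"field": "medium", "row": "Sample mounting and positioning: imaging/scanning medium", "type": "text", "modality": "both"},
    {"field": "multiplexed", "row": "Sample mounting and positioning: whether multiplexed scanning was performed", "type": "boolean", "modality": "uct3d"},
    {"field": "n_multiplexed", "row": "Sample mounting and positioning: how many animals were imaged simultaneously", "type": "integer", "modality": "uct3d", "required_if": {"field": "multiplexed", "equals": true}},
    {"field": "tube_potential_kv", "row": "X-ray source: X-ray tube potential (kV)", "type": "number", "modality": "both"},
    {"field": "tube_current_ua", "row": "X-ray source: X-ray tube current (uA)", "type": "number", "modality": "both"},
    {"field": "filter_used", "row": "X-ray source: whether filtering was performed to reduce beam hardening", "type": "boolean", "modality": "both"},
    {"field": "filter_type", "row": "X-ray source: type of filter used", "type": "text", "modality": "both", "required_if": {"field": "filter_used", "equals": true}},
    {"field": "exposure_s", "row": "X-ray detector: exposure time (s)", "type": "number", "modality": "xray2d"},
    {"field": "integration_ms", "row": "X-ray detector: integration time (ms)", "type": "number", "modality": "uct3d"},
    {"field": "frames_averaged", "row": "X-ray detector: number of frames used for averaging", "type": "integer", "modality": "both"},
    {"field": "projections_per_revolution", "row": "X-ray detector: number of projections per revolution", "type": "integer", "modality": "uct3d"},
    {"field": "source_distance_cm", "row": "X-ray detector: distance between the X-ray source and the specimen (cm)", "type": "number", "modality": "xray2d"},
    {"field": "pixel_or_voxel_size_um", "row": "X-ray detector: pixel/voxel size (um)", "type": "number", "modality": "both"},
    {"field": "detector_description", "row": "X-ray detector: detector size (mm) and mega pixel number", "type": "text", "modality": "xray2d"},
    {"field": "calibration_method", "row": "Phantom calibration: calibration method used for measuring bone density", "type": "text", "modality": "both"},
    {"field": "machine_make_model", "row": "Other: machine make and model", "type": "text", "modality": "both"}
  ]
}
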