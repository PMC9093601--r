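# Declarative ROI recipes for the eight study tracts.
# Two midline and six bilateral recipes expand to 14 tract instances per
# subject. Placements cite named anatomical structures and are resolved
# against whatever reference geometry supplies those structure masks.
# Anterior-posterior fractions are measured along world +y (RAS+).
- tract: gCC
  laterality: midline
  gates:
    # genu: anterior 1/6 of the corpus callosum length, drawn sagittally
    - polarity: AND
      plane: sagittal
      placement: {type: fraction, structure: corpus_callosum, edge: anterior, from: 0.0, to: 0.166667}
      extent: structure
      side: n/a
    # exclude fibres lateral to the corticospinal tract, both sides
    - polarity: NOT
      plane: parasagittal
      placement: {type: lateral_of, structure: corticospinal_tract}
      extent: entire
      side: both
- tract: bCC
  laterality: midline
  gates:
    # body: from 1/6 to 3/4 of the callosal length, excluding genu and
    # splenium (the splenium being the posterior 1/4)
    - polarity: AND
      plane: sagittal
      placement: {type: fraction, structure: corpus_callosum, edge: anterior, from: 0.166667, to: 0.75}
      extent: structure
      side: n/a
    # full axial slice just beneath the body of the corpus callosum
    - polarity: NOT
      plane: axial
      placement: {type: slice, structure: corpus_callosum, edge: inferior, offset_mm: -4}
      extent: entire
      side: n/a
- tract: ATR
  laterality: bilateral
  gates:
    # coronal slice at the middle of the genu: anterior limb of the
    # internal capsule
    - polarity: AND
      plane: coronal
      placement: {type: at_center, structure: corpus_callosum}
      extent: structure
      extent_structure: anterior_limb_internal_capsule
      side: n/a
    # coronal slice at the anterior edge of the pons: entire thalamus
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: pons, edge: anterior}
      extent: structure
      extent_structure: thalamus
      side: n/a
    - polarity: NOT
      plane: sagittal
      placement: {type: midline}
      extent: entire
      side: n/a
    # coronal slice at the posterior thalamic edge, entire slice
    - polarity: NOT
      plane: coronal
      placement: {type: slice, structure: thalamus, edge: posterior}
      extent: entire
      side: n/a
- tract: IFO
  laterality: bilateral
  gates:
    # coronal slice at the anterior edge of the genu, entire slice
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: corpus_callosum, edge: anterior}
      extent: entire
      side: n/a
    # coronal slice halfway along the parieto-occipital region: occipital
    # lobe
    - polarity: AND
      plane: coronal
      placement: {type: at_center, structure: occipital_lobe}
      extent: structure
      extent_structure: occipital_lobe
      side: n/a
    - polarity: NOT
      plane: sagittal
      placement: {type: midline}
      extent: entire
      side: n/a
- tract: ILF
  laterality: bilateral
  gates:
    # coronal slice at the posterior edge of the cingulum: occipital lobe
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: cingulum, edge: posterior}
      extent: structure
      extent_structure: occipital_lobe
      side: n/a
    # most posterior slice where the temporal lobe separates from the
    # frontal lobe: anterior temporal lobe
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: temporal_lobe, edge: posterior}
      extent: structure
      extent_structure: anterior_temporal_lobe
      side: n/a
    # same slice, everything except the anterior temporal lobe
    - polarity: NOT
      plane: coronal
      placement: {type: slice, structure: temporal_lobe, edge: posterior}
      extent: complement_structure
      extent_structure: anterior_temporal_lobe
      side: n/a
    - polarity: NOT
      plane: sagittal
      placement: {type: midline}
      extent: entire
      side: n/a
- tract: PLIC
  laterality: bilateral
  gates:
    # axial slice where the posterior limb is largest (its centre)
    - polarity: AND
      plane: axial
      placement: {type: at_center, structure: plic}
      extent: structure
      extent_structure: plic
      side: n/a
    # most inferior axial slice where the posterior limb is still visible
    # (one slab inward of the geometric tip, where the limb is still a
    # full cross-section rather than a partial-volume tail)
    - polarity: AND
      plane: axial
      placement: {type: slice, structure: plic, edge: inferior, offset_mm: 5}
      extent: structure
      extent_structure: plic
      side: n/a
    # full axial slice at the condensed corticospinal tract in the
    # brainstem
    - polarity: NOT
      plane: axial
      placement: {type: at_center, structure: brainstem}
      extent: entire
      side: n/a
- tract: PTR
  laterality: bilateral
  gates:
    # coronal slice at the posterior edge of the cingulum: periventricular
    # anterior-posterior fibres
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: cingulum, edge: posterior}
      extent: entire
      side: n/a
    # parasagittal slice at the lateral edge of the thalamus: entire
    # thalamus
    - polarity: AND
      plane: parasagittal
      placement: {type: slice, structure: thalamus, edge: lateral}
      extent: structure
      extent_structure: thalamus
      side: both
    - polarity: NOT
      plane: coronal
      placement: {type: slice, structure: thalamus, edge: anterior}
      extent: entire
      side: n/a
    - polarity: NOT
      plane: axial
      placement: {type: slice, structure: thalamus, edge: inferior}
      extent: entire
      side: n/a
- tract: UF
  laterality: bilateral
  gates:
    # axial slice where the condensed cephalic-caudal fibres are distinct
    # in the temporal lobe
    - polarity: AND
      plane: axial
      placement: {type: at_center, structure: uncinate_stem}
      extent: structure
      extent_structure: temporal_lobe
      side: n/a
    # coronal slice anterior to the condensed fibres: inferior frontal lobe
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: uncinate_stem, edge: anterior}
      extent: structure
      extent_structure: frontal_lobe
      side: n/a
    # same slice: temporal lobe
    - polarity: AND
      plane: coronal
      placement: {type: slice, structure: uncinate_stem, edge: anterior}
      extent: structure
      extent_structure: temporal_lobe
      side: n/a
    # coronal slice posterior to the condensed fibres, entire slice
    - polarity: NOT
      plane: coronal
      placement: {type: slice, structure: uncinate_stem, edge: posterior}
      extent: entire
      side: n/a
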