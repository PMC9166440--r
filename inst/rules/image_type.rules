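# Image-type retrieval rules: one OR of phrase queries per relevant image
# type, combined by classify_relevance() into the pre-processing filter.
# Order matters for classify_axis(): composite studies are listed before
# their components so "CT chest abdomen and pelvis" is not claimed by the
# plain CT chest rule. These term lists are editable approximations; tune
# them to the phrasing of your local report corpus.
axis: image_type
default: null
ct_chest_abdomen_pelvis: OR("ct chest abdomen and pelvis"; "ct of the chest abdomen and pelvis"; "ct chest abdomen pelvis")
ct_abdomen_pelvis: OR("ct abdomen and pelvis"; "ct of the abdomen and pelvis"; "ct abdomen pelvis")
ct_chest: OR("ct chest"; "ct of the chest"; "ct thorax")
ct_head: OR("ct head"; "ct of the head"; "ct brain")
chest_xray: OR("chest x ray"; "chest radiograph"; "pa and lateral chest"; "portable chest"; "two view chest")
bone_scan: OR("bone scan"; "whole body bone scan"; "skeletal scintigraphy")
pet: OR("pet ct"; "pet scan"; "positron emission tomography")
mri_brain: OR("mri brain"; "mri of the brain"; "mr brain")
mri_body: OR("mri body"; "mri of the abdomen"; "mri abdomen"; "mr body")
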