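# Mini radiological-entity term list (surface <TAB> category).
# A small self-contained stand-in for full ontology dictionaries; covers the
# worked-example vocabulary plus the synthetic-corpus vocabulary.
opacity	finding
consolidation	finding
edema	finding
effusion	finding
atelectasis	finding
atelactases	finding
lesion	finding
cyst	finding
nodule	finding
mass	finding
hypodensity	finding
infiltrate	finding
hemorrhage	finding
pneumothorax	finding
fracture	finding
thickening	finding
increased signal	finding
signal abnormality	finding
focus	finding
pneumonia	finding
hyaline membrane disease	finding
microvascular angiopathy	finding
lacune	finding
malignancy	finding
infection	finding
abscess	finding
metastasis	finding
inflammation	finding
aspiration	finding
scarring	finding
granuloma	finding
calcification	finding
atherosclerotic changes	finding
lung	anatomy
carina	anatomy
atrium	anatomy
right atrium	anatomy
ventricle	anatomy
liver	anatomy
spleen	anatomy
kidney	anatomy
trachea	anatomy
esophagus	anatomy
aorta	anatomy
bladder	anatomy
colon	anatomy
sternum	anatomy
clavicle	anatomy
diaphragm	anatomy
mediastinum	anatomy
hilum	anatomy
stomach	anatomy
duodenum	anatomy
lobe	anatomy
cortex	anatomy
cerebellar peduncle	anatomy
inferior cerebellar peduncle	anatomy
periventricular white matter	anatomy
centrum semi-ovale	anatomy
right lower lobe	anatomy
left lateral ventricle	anatomy
corona radiata	anatomy
brain parenchyma	anatomy
svc	anatomy
mid svc	anatomy
foramen magnum	anatomy
basal ganglia	anatomy
thalamus	anatomy
pons	anatomy
humerus	anatomy
femur	anatomy
catheter	device
pic catheter	device
picc line	device
uv line	device
ett tube	device
endotracheal tube	device
pacemaker	device
drain	device
stent	device
feeding tube	device
central line	device
chest tube	device
consistent with	hedge
concerning for	hedge
suggestive of	hedge
worrisome for	hedge
compatible with	hedge
suspicious for	hedge
likely	certainty_descriptor
probable	certainty_descriptor
possible	certainty_descriptor
questionable	certainty_descriptor
terminates	position_status
terminating	position_status
tip	position_status
positioned	position_status
advanced	position_status
located	position_status
high	relative_position
low	relative_position
anterior	relative_position
posterior	relative_position
medial	relative_position
lateral	relative_position
proximal	relative_position
distal	relative_position
inferior	location_descriptor
superior	location_descriptor
right	location_descriptor
left	location_descriptor
movement of the right foot	process
swallowing	process
respiration	process
inspiration	process
expiration	process
valsalva maneuver	process
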