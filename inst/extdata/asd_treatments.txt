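# ASD treatment gazetteer: drugs, supplements and psychosocial therapies
# commonly discussed in autism parent forums, one term per line.
chelation
chelating
chelator
probiotics
probiotic
zinc
enzymes
enzyme
melatonin
special education
antibiotics
antibiotic
speech therapy
early intervention
magnesium
activated charcoal
charcoal
nystatin
calcium
progesterone
cod liver oil
molybdenum glycinate chelate
sensory integration
aloe vera
pyridoxine hydrochloride
risperdal
risperidone
homeopathy
vitamin
vitamins
thimerosal
vitamin a
vitamin b6
vitamin b12
vitamin c
vitamin d
vitamin e
b6
b12
b-12
folic acid
folinic acid
fish oil
omega 3
omega 3 fatty acids
epsom salts
epsom salt bath
glutathione
dmg
tmg
dimethylglycine
trimethylglycine
secretin
methyl b12
iron
selenium
potassium
taurine
carnitine
l-carnitine
carnosine
l-carnosine
inositol
5-htp
gaba
dmsa
dmps
edta
alpha lipoic acid
milk thistle
grapefruit seed extract
olive leaf extract
oil of oregano
caprylic acid
candida diet
yeast treatment
antifungals
antifungal
diflucan
fluconazole
ketoconazole
amphotericin
augmentin
amoxicillin
vancomycin
valtrex
acyclovir
prozac
fluoxetine
zoloft
sertraline
paxil
celexa
lexapro
ritalin
methylphenidate
concerta
adderall
strattera
atomoxetine
clonidine
tenex
guanfacine
abilify
aripiprazole
zyprexa
olanzapine
seroquel
quetiapine
haldol
haloperidol
depakote
valproic acid
lamictal
lamotrigine
topamax
topiramate
keppra
levetiracetam
naltrexone
low dose naltrexone
oxytocin
ivig
hbot
hyperbaric oxygen therapy
gfcf diet
gluten free diet
casein free diet
gluten free casein free diet
specific carbohydrate diet
feingold diet
ketogenic diet
elimination diet
digestive enzymes
cal-mag
cod liver oil capsules
efalex
super nu-thera
nu-thera
coenzyme q10
coq10
melatonin drops
aba
applied behavior analysis
aba therapy
floortime
son-rise program
rdi
relationship development intervention
pecs
picture exchange communication system
teacch
occupational therapy
physical therapy
music therapy
art therapy
play therapy
social skills training
social skills group
auditory integration training
ait
vision therapy
craniosacral therapy
chiropractic
acupuncture
neurofeedback
biofeedback
hippotherapy
therapeutic horseback riding
swimming lessons
sign language
speech and language therapy
behavior therapy
cognitive behavioral therapy
respite care
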