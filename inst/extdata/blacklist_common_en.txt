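# Common-word blacklist for the dictionary tagger: lexicon terms whose
# lowercase form collides with ordinary English words. Membership is
# case-insensitive; short all-uppercase lexicon terms (gene-symbol style)
# are matched case-sensitively by the tagger and are not filtered here.
was
all
can
for
not
but
set
act
map
ice
impact
large
damage
arc
cat
rat
mice
fat
lead
iron
gold
light
dark
sharp
aim
fix
hip
cope
camp
mask
flame
spring
rest
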