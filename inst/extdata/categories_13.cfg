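# Default 13-category scheme for meat identification.
# Format: category: taxon1, taxon2, ...
# Taxa are matched case-insensitively as whole tokens against species names
# and explicit taxon labels. Membership is a representative starting point;
# edit freely. A taxon may appear under only one category.
pork: Sus
beef: Bos, Bubalus, Bison
mutton: Capra, Ovis, Pseudois
chicken: Gallus
rabbit: Oryctolagus, Lepus
rat: Rattus, Mus
venison: Cervus, Capreolus, Odocoileus, Muntiacus, Mazama, Rusa, Hydropotes, Rangifer
horse: Equus
camel: Camelus
bear: Ursus
dog: Canis, Nyctereutes
cat: Felis
fox: Vulpes
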