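component,label,category
floor,earth,natural
floor,sand,natural
floor,dung,natural
floor,"earth, sand",natural
floor,"earth, sand, dung",natural
floor,wood planks,rudimentary
floor,palm,rudimentary
floor,bamboo,rudimentary
floor,"palm, bamboo",rudimentary
floor,parquet,finished
floor,polished wood,finished
floor,parquet or polished wood,finished
floor,vinyl,finished
floor,asphalt strips,finished
floor,vinyl or asphalt strips,finished
floor,cement,finished
floor,carpet,finished
floor,ceramic tiles,finished
wall,mud,natural
wall,sticks,natural
wall,cane,natural
wall,palm,natural
wall,tin,natural
wall,cardboard,natural
wall,paper,natural
wall,thatch,natural
wall,straw,natural
wall,no walls,natural
wall,bamboo with mud,rudimentary
wall,stone with mud,rudimentary
wall,trunks with mud,rudimentary
wall,uncovered adobe,rudimentary
wall,plywood,rudimentary
wall,reused wood,rudimentary
wall,unburnt bricks,rudimentary
wall,cement,finished
wall,cement blocks,finished
wall,stone with lime,finished
wall,stone with cement,finished
wall,stone with lime or cement,finished
wall,bricks,finished
wall,burnt bricks,finished
wall,covered adobe,finished
wall,wood planks,finished
wall,wood shingles,finished
roof,grass,natural
roof,thatch,natural
roof,palm leaves,natural
roof,sod,natural
roof,straw,natural
roof,no roof,natural
roof,palm,rudimentary
roof,bamboo,rudimentary
roof,wood planks,rudimentary
roof,cardboard,rudimentary
roof,tarpaulin,rudimentary
roof,plastic,rudimentary
roof,metal,finished
roof,wood,finished
roof,ceramic tiles,finished
roof,cement,finished
roof,shingles,finished
roof,slate,finished
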