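"species","genus","family","category"
"g11_sp01","g11","Urticaceae","VU"
"g06_sp02","g06","Lauraceae","NT"
"g04_sp03","g04","Annonaceae","VU"
"g04_sp04","g04","Annonaceae","LC"
"g08_sp05","g08","Moraceae","VU"
"g04_sp06","g04","Annonaceae","LC"
"g13_sp07","g13","Orchidaceae","VU"
"g06_sp08","g06","Lauraceae","VU"
"g10_sp09","g10","Urticaceae","CR"
"g01_sp10","g01","Rubiaceae","VU"
"g10_sp11","g10","Urticaceae","LC"
"g05_sp12","g05","Annonaceae","VU"
"g04_sp13","g04","Annonaceae","LC"
"g03_sp14","g03","Rubiaceae","VU"
"g08_sp15","g08","Moraceae","LC"
"g11_sp16","g11","Urticaceae","EN"
"g01_sp17","g01","Rubiaceae","LC"
"g11_sp18","g11","Urticaceae","LC"
"g12_sp19","g12","Orchidaceae","LC"
"g06_sp20","g06","Lauraceae","EN"
"g01_sp21","g01","Rubiaceae","LC"
"g01_sp22","g01","Rubiaceae","VU"
"g04_sp23","g04","Annonaceae","EN"
"g11_sp24","g11","Urticaceae","LC"
"g07_sp25","g07","Lauraceae","LC"
"g06_sp26","g06","Lauraceae","NT"
"g02_sp27","g02","Rubiaceae","EN"
"g07_sp28","g07","Lauraceae","LC"
"g01_sp29","g01","Rubiaceae","VU"
"g01_sp30","g01","Rubiaceae","LC"
"g08_sp31","g08","Moraceae","CR"
"g06_sp32","g06","Lauraceae","LC"
"g12_sp33","g12","Orchidaceae","EN"
"g09_sp34","g09","Moraceae","LC"
"g04_sp35","g04","Annonaceae","VU"
"g04_sp36","g04","Annonaceae","LC"
"g01_sp37","g01","Rubiaceae","VU"
"g09_sp38","g09","Moraceae","EN"
"g01_sp39","g01","Rubiaceae","CR"
"g02_sp40","g02","Rubiaceae","LR/CD"
"g11_sp41","g11","Urticaceae","VU"
"g10_sp42","g10","Urticaceae","LC"
"g02_sp43","g02","Rubiaceae","LC"
"g13_sp44","g13","Orchidaceae","VU"
"g11_sp45","g11","Urticaceae","VU"
"g08_sp46","g08","Moraceae","VU"
"g13_sp47","g13","Orchidaceae","VU"
"g06_sp48","g06","Lauraceae","LC"
"g02_sp49","g02","Rubiaceae","LC"
"g02_sp50","g02","Rubiaceae","VU"
"g01_sp51","g01","Rubiaceae","EN"
"g04_sp52","g04","Annonaceae","LC"
"g08_sp53","g08","Moraceae","LC"
"g08_sp54","g08","Moraceae","VU"
"g14_sp55","g14","Orchidaceae","VU"
"g04_sp56","g04","Annonaceae","DD"
"g01_sp57","g01","Rubiaceae","VU"
"g12_sp58","g12","Orchidaceae","LC"
"g08_sp59","g08","Moraceae","VU"
"g06_sp60","g06","Lauraceae","LC"
"g01_sp61","g01","Rubiaceae","LC"
"g08_sp62","g08","Moraceae","VU"
"g13_sp63","g13","Orchidaceae","NT"
"g02_sp64","g02","Rubiaceae","LC"
"g06_sp65","g06","Lauraceae","VU"
"g07_sp66","g07","Lauraceae","VU"
"g10_sp67","g10","Urticaceae","LC"
"g04_sp68","g04","Annonaceae","LC"
"g06_sp69","g06","Lauraceae","VU"
"g06_sp70","g06","Lauraceae","LC"
"g02_sp71","g02","Rubiaceae","LC"
"g12_sp72","g12","Orchidaceae","VU"
"g02_sp73","g02","Rubiaceae","EN"
"g08_sp74","g08","Moraceae","LC"
"g06_sp75","g06","Lauraceae","EN"
"g04_sp76","g04","Annonaceae","EN"
"g06_sp77","g06","Lauraceae","LC"
"g01_sp78","g01","Rubiaceae","VU"
"g02_sp79","g02","Rubiaceae","VU"
"g12_sp80","g12","Orchidaceae","LC"
"g12_sp81","g12","Orchidaceae","EN"
"g12_sp82","g12","Orchidaceae","VU"
"g08_sp83","g08","Moraceae","VU"
"g01_sp84","g01","Rubiaceae","EN"
"g04_sp85","g04","Annonaceae","LC"
"g08_sp86","g08","Moraceae","VU"
"g09_sp87","g09","Moraceae","LC"
"g06_sp88","g06","Lauraceae","LC"
"g01_sp89","g01","Rubiaceae","EN"
"g11_sp90","g11","Urticaceae","VU"
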