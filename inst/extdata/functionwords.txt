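# closed-class function words delimiting term-candidate runs
a
about
after
against
all
also
although
among
an
and
another
any
are
as
at
be
because
been
before
being
best
between
both
but
by
can
could
did
do
does
during
each
either
even
every
for
from
had
has
have
he
her
here
his
how
however
i
if
in
into
is
it
its
just
least
less
may
might
more
most
must
my
neither
no
nor
not
of
on
only
onto
or
other
our
over
per
same
shall
she
should
since
so
some
still
such
than
that
the
their
them
then
there
these
they
this
those
through
to
too
under
unless
until
up
upon
very
was
we
were
what
when
where
whether
which
while
who
whom
whose
will
with
within
without
would
yet
you
your
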